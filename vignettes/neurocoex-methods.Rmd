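---
title: "Methods: co-expression, network nulls, rank products and enrichment in neurocoex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression, network nulls, rank products and enrichment in neurocoex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

A recurring observation in neurogenomics is that genes annotated to immune
system (IS) processes are broadly expressed in the brain and keep turning up
in neural-specific functions. `neurocoex` implements the statistical
machinery needed to ask whether such a labelled gene set behaves as a
*coordinated regulatory unit* in bulk expression data, rather than as a
collection of independently recruited genes:

1. Is the set's internal co-expression higher than chance?
2. Is it organised as a clustered network rather than scattered pairs?
3. When the system is stimulated, do set members respond together?

Each question gets a dedicated statistic with an explicit resampling or
rewiring null, so that "higher than chance" always refers to a concrete,
reproducible reference distribution.

# Set-level co-expression

Given a genes-by-samples matrix, `correlation_matrix()` computes the Pearson
correlation $R_{ij}$ over samples for every gene pair. The set-level summary
is the **median pairwise correlation**: over all $\binom{|A|}{2}$ unordered
pairs within a set $A$, or over all $|A|\times|B|$ cross pairs for two
disjoint sets (sets are made disjoint beforehand with `enforce_disjoint()`,
which removes genes annotated to both so the between-set estimate is not
inflated by shared members). The median, not the mean, is used: pairwise
correlation distributions in expression data are heavy-tailed, and the
median is insensitive to the handful of extreme pairs.

The null is constructed by `resampled_null()`: each of $n$ draws samples a
random gene set (or pair of disjoint sets) of the *same size(s)* uniformly
without replacement from the background population and records the same
median under the same pairing mode. `summarize_null()` then reports

* $Z = (m_{\mathrm{obs}} - \bar m_{\mathrm{null}}) / s_{\mathrm{null}}$,
  with $s$ the sample standard deviation (denominator $n-1$), and
* the empirical tail probability with the add-one correction
  $p = (1 + \#\{m_{\mathrm{null}} \ge m_{\mathrm{obs}}\}) / (1 + n)$.

The add-one estimator never returns 0: with $n$ draws the smallest
reportable $p$ is $1/(n+1)$. A Monte Carlo $p$ of exactly zero is a
reporting artifact, not evidence; the floor makes the resolution of the
estimate explicit. The default tail is upper (coordinated expression);
`tail = "lower"` is available. Defaults follow the reference analysis
design: 10,000 resamples.

Genes with zero variance across samples have no defined correlation; they
are flagged, excluded from medians, removed from resampling backgrounds and
never form network edges. Correlations are computed on (normalized) values
as-is; a `log2_transform` flag exists because intensity data are sometimes
correlated on the log scale, but no transformation is the default.

# Thresholded networks and the rewiring null

`build_threshold_graph()` connects gene pairs with $R_{ij} > t$ — strictly
above, so a pair at exactly the cutoff is excluded — using signed
correlations by default (`absolute = TRUE` thresholds $|R|$; strong negative
correlation is a different biological statement from co-activation).
The focal set restricts the graph: `within_set` keeps only focal–focal
edges (the "IS–IS network"), `incident` keeps every edge touching the set.
Clustering statistics are computed on the within-set graph; the incident
graph exists for the edge-composition test below. Both scopes are exposed
because published network figures are often ambiguous about which graph a
clustering number refers to.

The per-node statistic is the Watts–Strogatz **local clustering
coefficient** $C_i = 2 e_i / (k_i (k_i - 1))$, the fraction of realized
edges among a node's immediate neighbours. Nodes of degree $< 2$ have no
neighbour pair; they are reported as undefined and excluded from the mean
rather than scored 0, which would deflate the observed and null means by an
amount that depends only on the degree sequence, not on clustering.

The reference distribution for the mean coefficient must control for the
degree sequence — heterogeneous degrees alone produce clustering. We use
**double-edge-swap rewiring**: repeatedly pick two edges and exchange their
endpoints, rejecting swaps that would create self-loops or parallel edges,
with at least 10 swap attempts per edge per null network. This preserves
the node count, edge count and the exact degree sequence (asserted on every
draw), unlike stub-matching configuration sampling, which needs multi-edge
rejection and biases small dense graphs. Graphs that admit no valid swap
(a single triangle, a complete clique) reproduce themselves; the ratio is
then 1 and $p$ is 1 by construction, which is the correct statement that
such a graph carries no testable excess clustering. The summary is the
ratio of observed to expected mean clustering plus the add-one empirical
$p$; `threshold_sweep()` repeats this over a ladder of cutoffs, reporting
cutoffs at which no edge survives as absent rather than inventing a value.

The **edge-composition test** (`edge_composition_test()`) asks a different
question: among edges incident to the focal set, is the proportion joining
two focal genes higher than if a focal gene chose partners uniformly among
the other nodes? The null proportion is $(n_{\mathrm{focal}}-1)/(n-1)$ and
the statistic is a 1-df chi-square over the two cells (within / cross), no
continuity correction. This null expectation is one defensible choice among
several (the published analyses this mirrors do not specify theirs); it is
a parameter of interpretation, not of fitting.

# Rank-products differential expression

For a two-condition comparison, `rank_product()` ranks genes by log2 fold
change within each case–control comparison (average ranks on ties) and
summarizes each gene by the geometric mean of its ranks — small rank
products mean consistent extremeness across comparisons, a statistic that is
robust for very small replicate numbers. With equal replicate counts the
comparisons are the $k$ pairs case$_i$/control$_i$; with unequal counts all
case$\times$control pairings are used (the unpaired convention of the
rank-products literature). The paired form is preferred whenever available
because the permutation null below shuffles comparisons independently, which
is only a faithful null when comparisons share no replicates.

`permutation_pvalues()` shuffles the gene assignment independently within
every comparison, recomputes all rank products, and pools null values
across genes and permutations:
$p(g) = (1 + \#\{rp_{\mathrm{null}} \le rp_g\}) / (1 + B \cdot G)$,
plus the expected-false-positive ratio
$\mathrm{pfp}(g) = (\#\{rp_{\mathrm{null}} \le rp_g\}/B) / \mathrm{rank}(g)$,
the rank-products analogue of FDR. The downstream hit list defaults to
$p < 0.05$ on the up-regulation tail.

# Monte Carlo enrichment

`mc_enrichment()` contrasts the number of hit-list genes annotated to each
category with the counts in equally sized random gene lists drawn without
replacement from a fixed background universe (at least 10,000 draws in the
reference design; the implementation enforces $\ge$ 1,000). Expected counts
and their SDs come from the same draws; $p$ is upper-tail with the add-one
floor. Although the hypergeometric tail is available in closed form, the
Monte Carlo route is the implemented method — the closed form serves as the
independent oracle in the test suite, which is exactly the role it should
have: two routes to the same quantity, one checking the other.

Multiple testing uses Benjamini–Hochberg step-up via `bh_adjust()`, with an
explicit `m` that may exceed the number of p-values supplied. This
reproduces the convention of adjusting "against" a fixed family of tests
(e.g. 21 subcategories) even when only a subset is reported.

Annotation tables are gene-by-category incidence structures over an
explicit background. `propagate_annotations()` closes annotations upward
over `is_a` ontology links (each gene counted once per term regardless of
path multiplicity; cycles are an error, reported with a witness). Only
`is_a` is propagated by default — parent assignment is the only relation
the upstream annotation convention names — with `part_of` available behind
a flag. The packaged 31-gene table of TNF-alpha-responsive immune genes
(`load_tnf_is_annotations()`) provides a fixed, hand-checkable worked
example for the counting routines.

# The synthetic-data generator

Because the real datasets behind this kind of study are external and large,
every stage is validated on synthetic data with known structure
(`generate_module_matrix()`, `generate_de_experiment()`).

**Correlation modules** use a single-factor Gaussian model: for module $m$
with target correlation $\rho$,
$x_{gs} = \sqrt{\rho}\, f_{ms} + \sqrt{1-\rho}\,\varepsilon_{gs}$ with
independent standard normal factor and noise, so the expected within-module
correlation is exactly $\rho$ and between-module correlation is 0. A
Gaussian model suffices because every downstream statistic is rank- or
correlation-based; count-scale noise would add realism the statistics are
insensitive to.

The canonical study instance (`module_study_config()`) is 2,000 genes by
100 samples with three $\rho = 0.8$ modules: a 40-gene module exclusive to
the "IS" set, a 120-gene module shared 90/30 between "IS" and "NS", and a
100-gene unlabelled module representing co-expression structure in the
background. The proportions are not arbitrary. Sample correlations between
genes of two *independent* modules concentrate around
$\rho \cdot \hat r(f_1, f_2)$, where $\hat r$ is the sample correlation of
the two factors — a single draw of SD $\approx 1/\sqrt{n_{\mathrm{samples}}}$
whose sign is random. Two consequences drive the layout:

* within-module pairs must exceed half of all within-set pairs, so the
  within-set median sits inside the correlated block and cannot be dragged
  across zero by an unlucky factor draw;
* the shared module must contribute more cross-set pairs than the
  exclusive-module block does ($90 \cdot 30 > 40 \cdot 30$), so the planted
  positive IS–NS coupling dominates the sign-random block.

Without these constraints the generator would claim to plant a positive
between-set coupling while actually producing one whose sign flips from
seed to seed — an emulation bug, not a property of the method under test.

**Differential expression** uses log-normal intensities: control
log-values are standard normal; a planted fraction $\pi$ of genes gets a
case-side shift of $\delta\sqrt{2}$ on the log scale. The effect size
$\delta$ is expressed in SD units of a single case-versus-control log fold
change (whose SD is $\sqrt 2$ under unit per-replicate noise): an effect
"two SD strong" means two SDs of the quantity actually being ranked.
Defaults are $\pi = 0.05$, $\delta = 2$, three replicates per group.
Planted genes can be concentrated inside a labelled set to rehearse the
full chain from stimulation to enrichment.

Truth labels are always emitted with the data, so tests never re-derive
ground truth from the method being tested.

# Numerical and design choices

* **Strict inequalities.** "Above a threshold" ($R > t$) and "lower than
  the negative controls" are strict, following the literal reading of the
  procedures they implement; values exactly at a boundary are kept.
* **Probe handling.** Probes matching multiple genes are excluded before
  averaging; the negative-control filter runs at probe level before
  summarization; per-sample total normalization runs last and is
  idempotent. Missing values are rejected at load — there is no principled
  imputation rule to apply.
* **Seeds.** Every stochastic operation takes a single integer seed and
  restores the caller's RNG state; identical seeds give bit-identical
  results, and observed statistics never depend on the seed (only null
  distributions and p-values do).
* **Ties.** Fold-change ties receive average ranks; the BH step-up is
  computed over the supplied vector with ranks within that vector.
* **Degenerate inputs.** Zero-variance genes, empty graphs, rigid graphs,
  all-focal partitions, empty categories and all-zero samples each have a
  defined behaviour (exclusion, absent-threshold reporting, ratio 1,
  error, $p = 1$, error respectively) rather than an accidental one.

# Validation strategy and problem sizes

The test suite validates each stochastic estimator against an independent
oracle: exhaustive subset enumeration for the resampling null (5-gene
background), exhaustive $(3!)^2$ rank configurations for the permutation
p-values, hypergeometric closed forms for Monte Carlo enrichment,
brute-force step-up for BH, and brute-force triangle counting for
clustering coefficients. Calibration is checked by rejection-rate
experiments under the null (200 replicate datasets, exact binomial 99%
acceptance bands) and by the unit clustering ratio on Erdős–Rényi graphs.
Structure recovery runs on the canonical 2,000-gene instance; the threshold
sweep is additionally exercised at $\rho = 0.9$, where the $R > 0.9$ graph
is populated (at $\rho = 0.8$ with 100 samples, sample correlations
concentrate near 0.8 with SD $\approx$ 0.04, so the 0.9 cutoff correctly
comes back absent). Null-ensemble sizes in tests (199–499 networks,
199–2,000 resamples) are chosen so that the add-one floor sits comfortably
below the significance levels being asserted while the full suite stays
fast; the package defaults remain at the reference design's 10,000.

# Limitations

* The generator is Gaussian/log-normal: it emulates correlation and rank
  structure, not count noise, batch effects, outlier samples or
  developmental trajectories. Passing tests demonstrate the statistics are
  implemented correctly and calibrated under the model they assume — not
  that real tissue data satisfy those assumptions.
* Pooled correlation over heterogeneous samples (regions × ages) is the
  implemented estimator; sample-subset masks are the only stratification
  offered.
* The edge-composition null expectation is one defensible definition; a
  different partner-choice model would change the chi-square.
* Weighted (WGCNA-style) co-expression, partial correlations, moderated
  t-statistics and topology-aware enrichment are out of scope by design.
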