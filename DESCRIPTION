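Package: neurocoex
Title: Co-Expression and Regulatory Clustering of Immune System Genes in
    the Nervous System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying coordinated expression of
    labelled gene sets (for example immune-system genes) in bulk expression
    data. Implements set-level median Pearson co-expression with Monte Carlo
    resampling nulls, thresholded co-expression networks with
    degree-preserving (double-edge-swap) clustering-coefficient nulls and an
    edge-composition chi-square test, rank-products differential expression
    with permutation p-values, and Monte Carlo gene-set enrichment with
    Benjamini-Hochberg adjustment. Includes loaders for expression matrices,
    probe maps, GMT gene sets, OBO ontologies and annotation tables, a
    synthetic-data generator with planted correlation modules and planted
    differential expression for end-to-end validation, and a single-config
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    fgsea,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
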