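#' Configuration for synthetic expression data
#'
#' Describes a gene-by-sample matrix with planted block-correlated modules
#' (single-factor Gaussian model) plus labelled gene sets, and optionally a
#' two-condition experiment with a planted fraction of up-regulated genes.
#'
#' @param n_genes Total number of genes.
#' @param n_samples Number of samples for the module matrix.
#' @param modules List of `list(size =, rho =)` entries; module sizes must
#'   sum to at most `n_genes` and each `rho` must lie in \[0, 1). Genes are
#'   assigned to modules in order, remaining genes are independent noise.
#' @param set_labels Named list mapping set labels (e.g. `"IS"`, `"NS"`) to
#'   gene indices in `1:n_genes`.
#' @param de_spec Optional list for the two-condition experiment:
#'   `n_case`, `n_control` (replicates per group), `planted_fraction`
#'   (fraction of genes up-regulated), `effect_size` (shift in SD units of a
#'   single-replicate log fold change), and optionally `within_set` (a label
#'   from `set_labels`; planted genes are then drawn inside that set first).
#' @param seed Integer seed used by the generators.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes, n_samples, modules = list(),
                             set_labels = list(), de_spec = NULL, seed = 1L) {
  sizes <- vapply(modules, function(m) as.integer(m$size), integer(1))
  rhos <- vapply(modules, function(m) as.numeric(m$rho), numeric(1))
  if (any(rhos < 0 | rhos >= 1)) stop("module rho must lie in [0, 1)")
  if (sum(sizes) > n_genes) stop("module sizes exceed n_genes")
  for (nm in names(set_labels)) {
    idx <- set_labels[[nm]]
    if (any(idx < 1 | idx > n_genes)) stop("set '", nm, "' indexes outside 1:n_genes")
  }
  if (!is.null(de_spec)) {
    needed <- c("n_case", "n_control", "planted_fraction", "effect_size")
    miss <- setdiff(needed, names(de_spec))
    if (length(miss)) stop("de_spec missing field(s): ", paste(miss, collapse = ", "))
    if (de_spec$planted_fraction * n_genes < 1)
      stop("planted_fraction too small: fewer than one planted gene")
  }
  structure(list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
                 modules = modules, set_labels = set_labels,
                 de_spec = de_spec, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a module-structured expression matrix
#'
#' Each module of size `s` and correlation `rho` is generated by the
#' single-factor model `x_gs = sqrt(rho) f_s + sqrt(1 - rho) e_gs` with
#' independent standard-normal factor and noise, so the expected pairwise
#' correlation within a module is `rho` and between modules is 0. Genes not
#' assigned to a module are independent standard normal noise.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `expr` (an [expression_matrix()]), `sets` (named list
#'   of gene-identifier sets from `set_labels`), and `truth` (data frame of
#'   gene, module assignment).
#' @export
generate_module_matrix <- function(cfg) {
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  samples <- sprintf("s%03d", seq_len(cfg$n_samples))
  module_of <- rep(0L, cfg$n_genes)
  x <- with_seed(cfg$seed, {
    m <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples),
                cfg$n_genes, cfg$n_samples)
    offset <- 0L
    for (k in seq_along(cfg$modules)) {
      s <- cfg$modules[[k]]$size; rho <- cfg$modules[[k]]$rho
      rows <- offset + seq_len(s)
      f <- stats::rnorm(cfg$n_samples)
      m[rows, ] <- sqrt(1 - rho) * m[rows, , drop = FALSE] +
        sqrt(rho) * matrix(f, s, cfg$n_samples, byrow = TRUE)
      module_of[rows] <- k
      offset <- offset + s
    }
    m
  })
  dimnames(x) <- list(genes, samples)
  sets <- lapply(cfg$set_labels, function(idx) genes[idx])
  list(expr = expression_matrix(x),
       sets = sets,
       truth = data.frame(gene = genes, module = module_of,
                          stringsAsFactors = FALSE))
}

#' Generate a two-condition experiment with planted up-regulation
#'
#' Expression values are log-normal: control log-values are standard normal;
#' for the planted fraction of genes, case log-values are shifted upward by
#' `effect_size * sqrt(2)` (the effect size is expressed in SD units of a
#' single case-versus-control log fold change, whose SD is `sqrt(2)` under
#' unit per-replicate noise). All other genes share the control
#' distribution. When `de_spec$within_set` names a labelled set, planted
#' genes are drawn from that set first (spilling over to other genes only if
#' the set is too small), emulating a condition that switches on a
#' functionally coherent module.
#'
#' @param cfg A [synthetic_config()] with a `de_spec`.
#' @return List with `case` and `control` ([expression_matrix()] objects)
#'   and `truth` (character vector of planted up-regulated gene ids).
#' @export
generate_de_experiment <- function(cfg) {
  if (is.null(cfg$de_spec)) stop("config has no de_spec")
  spec <- cfg$de_spec
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  n_planted <- floor(spec$planted_fraction * cfg$n_genes)
  shift <- spec$effect_size * sqrt(2)
  with_seed(cfg$seed + 1L, {
    pool <- seq_len(cfg$n_genes)
    if (!is.null(spec$within_set)) {
      inside <- cfg$set_labels[[spec$within_set]]
      planted <- if (length(inside) >= n_planted) sample(inside, n_planted)
                 else c(inside, sample(setdiff(pool, inside), n_planted - length(inside)))
    } else planted <- sample(pool, n_planted)
    ctrl <- matrix(stats::rnorm(cfg$n_genes * spec$n_control),
                   cfg$n_genes, spec$n_control,
                   dimnames = list(genes, sprintf("ctrl%02d", seq_len(spec$n_control))))
    case <- matrix(stats::rnorm(cfg$n_genes * spec$n_case),
                   cfg$n_genes, spec$n_case,
                   dimnames = list(genes, sprintf("case%02d", seq_len(spec$n_case))))
    case[planted, ] <- case[planted, , drop = FALSE] + shift
    list(case = expression_matrix(exp(case)),
         control = expression_matrix(exp(ctrl)),
         truth = genes[sort(planted)])
  })
}

#' Canonical module-study configuration
#'
#' The synthetic counterpart of a brain co-expression study: 2,000 genes by
#' 100 samples with three `rho = 0.8` correlation modules. The "IS" set
#' (130 genes) spans a 40-gene exclusive module plus 90 genes of a 120-gene
#' shared module; the "NS" set (140 genes) holds the remaining 30 genes of
#' the shared module plus 110 unstructured genes, so the IS-NS coupling is
#' carried by genuinely co-regulated shared-module pairs. A third,
#' unlabelled 100-gene module models co-expression structure in the
#' background population; all other genes are independent noise.
#'
#' The proportions are chosen so that the planted signals are identifiable
#' rather than sign-ambiguous: within-module pairs make up more than half of
#' all within-IS pairs (the within-set median then sits inside the
#' correlated block), and the shared module contributes more cross-set pairs
#' than the exclusive module does (pairs between two *independent* modules
#' have a correlation set by the sample correlation of their factors -- a
#' random sign -- and must stay in the minority).
#'
#' @param seed Integer seed.
#' @param n_genes,n_samples Overall dimensions (defaults 2000 and 100);
#'   module and set sizes scale proportionally.
#' @return A [synthetic_config()].
#' @export
module_study_config <- function(seed = 1L, n_genes = 2000, n_samples = 100) {
  f <- n_genes / 2000
  a <- max(4L, round(40 * f))          # IS-exclusive module
  b <- max(8L, round(120 * f))         # shared module, 75% IS / 25% NS
  cc <- max(4L, round(100 * f))        # unlabelled background module
  b_is <- round(0.75 * b)
  nn <- max(4L, round(110 * f))        # unstructured NS members
  synthetic_config(
    n_genes = n_genes, n_samples = n_samples,
    modules = list(list(size = a, rho = 0.8),
                   list(size = b, rho = 0.8),
                   list(size = cc, rho = 0.8)),
    set_labels = list(IS = 1:(a + b_is),
                      NS = c((a + b_is + 1):(a + b), (a + b + cc) + 1:nn)),
    seed = seed)
}

#' Canonical differential-expression study configuration
#'
#' The synthetic counterpart of a two-group stimulation experiment: 2,000
#' genes, 3 case and 3 control replicates, a planted fraction of 5%
#' up-regulated genes at effect size 2 (SD units of a single-replicate log
#' fold change).
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes (default 2000).
#' @param within_set Optional set label to concentrate planted genes in
#'   (requires `set_labels`).
#' @param set_labels Passed through to [synthetic_config()].
#' @return A [synthetic_config()].
#' @export
de_study_config <- function(seed = 1L, n_genes = 2000, within_set = NULL,
                            set_labels = list()) {
  synthetic_config(
    n_genes = n_genes, n_samples = 1L,
    set_labels = set_labels,
    de_spec = list(n_case = 3, n_control = 3, planted_fraction = 0.05,
                   effect_size = 2, within_set = within_set),
    seed = seed)
}
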