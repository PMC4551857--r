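# Fold-change matrix, one column per comparison, values log2(case/control).
# Equal replicate counts give the k paired comparisons case_i vs control_i
# (comparisons then share no replicates, which the permutation null
# requires); unequal counts fall back to all case x control pairings, the
# unpaired convention of the rank-products literature.
.fold_changes <- function(case, control) {
  genes <- rownames(case)
  if (is.null(genes) || is.null(rownames(control)) ||
      !setequal(genes, rownames(control)))
    stop("case and control matrices must cover the same gene universe")
  control <- unclass(control)[genes, , drop = FALSE]
  case <- unclass(case)[genes, , drop = FALSE]
  if (any(case <= 0) || any(control <= 0))
    stop("fold changes need strictly positive expression values")
  k1 <- ncol(case); k2 <- ncol(control)
  pairs <- if (k1 == k2) cbind(seq_len(k1), seq_len(k2))
           else as.matrix(expand.grid(seq_len(k1), seq_len(k2)))
  fc <- matrix(NA_real_, length(genes), nrow(pairs),
               dimnames = list(genes, NULL))
  for (idx in seq_len(nrow(pairs)))
    fc[, idx] <- log2(case[, pairs[idx, 1]]) - log2(control[, pairs[idx, 2]])
  fc
}

# Geometric mean of per-comparison ranks; direction +1 ranks the largest
# fold change first (up-regulation), -1 the smallest (down-regulation).
# Ties receive average ranks.
.rank_product_of <- function(fc, direction) {
  ranks <- apply(-direction * fc, 2, rank, ties.method = "average")
  exp(rowMeans(log(ranks)))
}

#' Rank products for two-class differential expression
#'
#' For each case-control comparison (the `k` paired comparisons when
#' replicate counts are equal, all `n_case x n_control` pairings otherwise),
#' genes are ranked by log2 fold change (rank 1 = most up-regulated for
#' `rp_up`, most down-regulated for `rp_down`; ties get average ranks). The
#' rank product of a gene is the geometric mean of its ranks across
#' comparisons; consistently extreme genes have rank products near 1.
#'
#' @param case,control [expression_matrix()] objects (or named matrices) on
#'   the same gene universe, strictly positive values, >= 1 column each.
#' @return Data frame with columns `gene`, `rp_up`, `rp_down`.
#' @export
rank_product <- function(case, control) {
  fc <- .fold_changes(case, control)
  data.frame(gene = rownames(fc),
             rp_up = .rank_product_of(fc, +1),
             rp_down = .rank_product_of(fc, -1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation p-values and false-positive proportions for rank products
#'
#' Each permutation independently shuffles the gene assignment within every
#' comparison column and recomputes all rank products, pooling the null
#' values across genes and permutations. For a gene with observed rank
#' product `rp`, `p = (1 + #\{null rp <= rp\}) / (1 + n_permutations x G)`
#' (add-one estimator). The estimated proportion of false positives is
#' `pfp = (expected null count per permutation) / (rank of the gene)`, the
#' rank-products analogue of FDR.
#'
#' @param rp_observed Numeric vector of observed rank products (one per
#'   gene, e.g. the `rp_up` column of [rank_product()]).
#' @param case,control The matrices the observed rank products came from.
#' @param direction `+1` for up-regulation, `-1` for down-regulation; must
#'   match how `rp_observed` was computed.
#' @param n_permutations Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return Data frame with columns `p` and `pfp`, rows aligned with
#'   `rp_observed`.
#' @export
permutation_pvalues <- function(rp_observed, case, control, direction = +1,
                                n_permutations = 100, seed = NULL) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  fc <- .fold_changes(case, control)
  G <- nrow(fc)
  null_rps <- with_seed(seed, {
    unlist(lapply(seq_len(n_permutations), function(b) {
      perm_fc <- apply(fc, 2, sample)
      .rank_product_of(perm_fc, direction)
    }), use.names = FALSE)
  })
  null_sorted <- sort(null_rps)
  counts <- findInterval(rp_observed, null_sorted)  # #{null <= observed}
  p <- (1 + counts) / (1 + n_permutations * G)
  pfp <- (counts / n_permutations) / rank(rp_observed, ties.method = "min")
  data.frame(p = p, pfp = pfp)
}

#' Rank-products differential expression analysis
#'
#' Runs [rank_product()] for both directions and attaches permutation
#' p-values and estimated false-positive proportions for each.
#'
#' @inheritParams rank_product
#' @inheritParams permutation_pvalues
#' @return Data frame with columns `gene`, `rp_up`, `p_up`, `pfp_up`,
#'   `rp_down`, `p_down`, `pfp_down`, in the input gene order.
#' @export
rank_product_test <- function(case, control, n_permutations = 100, seed = NULL) {
  rp <- rank_product(case, control)
  up <- permutation_pvalues(rp$rp_up, case, control, +1, n_permutations, seed)
  down <- permutation_pvalues(rp$rp_down, case, control, -1, n_permutations,
                              if (is.null(seed)) NULL else seed + 1L)
  data.frame(gene = rp$gene,
             rp_up = rp$rp_up, p_up = up$p, pfp_up = up$pfp,
             rp_down = rp$rp_down, p_down = down$p, pfp_down = down$pfp,
             stringsAsFactors = FALSE)
}
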