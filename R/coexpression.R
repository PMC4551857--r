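# Seed handling: every stochastic entry point takes an integer `seed`; the
# global RNG state is saved and restored so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

#' All-pairs Pearson correlation matrix
#'
#' Computes the Pearson correlation coefficient across samples for every
#' pair of genes. Genes with zero variance across samples yield undefined
#' (`NA`) entries; they are flagged in the `zero_variance` attribute and are
#' excluded from all downstream medians, resampling backgrounds and
#' threshold graphs.
#'
#' @param expr An [expression_matrix()] (genes x samples) with at least 3
#'   samples.
#' @param log2_transform Logical; apply `log2` before correlating (values
#'   must then be strictly positive). Default `FALSE`: correlations are taken
#'   on the (normalized) values as-is.
#' @return A `correlation_matrix`: symmetric numeric matrix with unit
#'   diagonal for non-degenerate genes, gene identifiers as dimnames, and a
#'   `zero_variance` attribute listing degenerate genes.
#' @export
correlation_matrix <- function(expr, log2_transform = FALSE) {
  m <- unclass(expr)
  if (ncol(m) < 3) stop("at least 3 samples are required to estimate correlations")
  if (log2_transform) {
    if (any(m <= 0)) stop("log2 transform requires strictly positive values")
    m <- log2(m)
  }
  v <- apply(m, 1, stats::var)
  zero_var <- rownames(m)[v == 0]
  R <- suppressWarnings(stats::cor(t(m)))
  R[zero_var, ] <- NA_real_
  R[, zero_var] <- NA_real_
  structure(R, zero_variance = zero_var, class = c("correlation_matrix", "matrix"))
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d genes (%d zero-variance)\n",
              nrow(x), length(attr(x, "zero_variance"))))
  invisible(x)
}

# All unordered within-set pairwise correlations (self-pairs never included),
# or all cross pairs when set_b is given. NA entries (zero-variance genes)
# are dropped.
.pair_correlations <- function(R, set_a, set_b = NULL) {
  if (is.null(set_b)) {
    sub <- unclass(R)[set_a, set_a, drop = FALSE]
    vals <- sub[upper.tri(sub)]
  } else {
    vals <- as.vector(unclass(R)[set_a, set_b, drop = FALSE])
  }
  vals[!is.na(vals)]
}

#' Median set-level co-expression
#'
#' Within-set mode (`set_b = NULL`): the median over all `|A|(|A|-1)/2`
#' unordered distinct pairs of `set_a`. Between-set mode: the median over
#' all `|A| x |B|` cross pairs (the sets are expected to have been made
#' disjoint beforehand, see [enforce_disjoint()]).
#'
#' @param R A [correlation_matrix()].
#' @param set_a Character vector of gene identifiers (>= 2 genes for
#'   within-set mode).
#' @param set_b Optional second gene set for between-set mode.
#' @return The median pairwise correlation (scalar).
#' @export
median_set_coexpression <- function(R, set_a, set_b = NULL) {
  missing <- setdiff(c(set_a, set_b), rownames(R))
  if (length(missing))
    stop("gene(s) not in correlation matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (is.null(set_b) && length(unique(set_a)) < 2)
    stop("within-set mode needs at least 2 genes")
  vals <- .pair_correlations(R, unique(set_a), if (!is.null(set_b)) unique(set_b))
  if (length(vals) == 0) stop("no defined gene pairs to take a median over")
  stats::median(vals)
}

#' Resampling null for set-level median co-expression
#'
#' Draws `n_resamples` random gene sets of the same size(s) as the observed
#' set(s), uniformly without replacement from the background, and records the
#' median pairwise correlation of each draw under the same pairing mode
#' (within-set, or between two disjoint random sets). Zero-variance genes are
#' removed from the background before sampling.
#'
#' @param R A [correlation_matrix()].
#' @param size_a Size of the (first) set.
#' @param size_b Optional size of the second set (between-set mode); the two
#'   random sets of a draw are disjoint.
#' @param background Character vector of gene identifiers to draw from.
#' @param n_resamples Number of random draws (the reference analyses use
#'   10,000).
#' @param seed Integer seed; the same seed reproduces the null exactly.
#' @return Numeric vector of `n_resamples` null medians.
#' @export
resampled_null <- function(R, size_a, size_b = NULL, background,
                           n_resamples = 10000, seed = NULL) {
  background <- setdiff(intersect(unique(background), rownames(R)),
                        attr(R, "zero_variance"))
  need <- size_a + if (is.null(size_b)) 0L else size_b
  if (length(background) < need)
    stop("background (", length(background), " usable genes) smaller than requested size ", need)
  Rm <- unclass(R)
  with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      draw <- sample(background, need)
      a <- draw[seq_len(size_a)]
      if (is.null(size_b)) {
        sub <- Rm[a, a, drop = FALSE]
        stats::median(sub[upper.tri(sub)], na.rm = TRUE)
      } else {
        stats::median(Rm[a, draw[(size_a + 1L):need], drop = FALSE], na.rm = TRUE)
      }
    }, numeric(1))
  })
}

#' Summarize an observed statistic against a resampling null
#'
#' Z-score uses the null mean and sample standard deviation (denominator
#' n-1). The empirical p-value uses the add-one estimator
#' `(1 + #exceedances) / (1 + n)` so it is never exactly zero; the tail is
#' upper by default (observed at least as large as the null).
#'
#' @param observed Observed statistic (e.g. a set median correlation).
#' @param null_values Numeric vector of resampled null statistics.
#' @param tail `"upper"` (default) or `"lower"`.
#' @return A `set_coexpression_result` list: `observed`, `null_mean`,
#'   `null_sd`, `z_score`, `p_empirical`, `tail`, `n_resamples`.
#' @export
summarize_null <- function(observed, null_values, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (length(null_values) == 0) stop("empty null distribution")
  mu <- mean(null_values)
  sdv <- stats::sd(null_values)
  z <- if (is.na(sdv) || sdv == 0) NA_real_ else (observed - mu) / sdv
  exceed <- if (tail == "upper") sum(null_values >= observed) else sum(null_values <= observed)
  p <- (1 + exceed) / (1 + length(null_values))
  structure(list(observed = observed, null_mean = mu, null_sd = sdv,
                 z_score = z, p_empirical = p, tail = tail,
                 n_resamples = length(null_values)),
            class = "set_coexpression_result")
}

#' @export
print.set_coexpression_result <- function(x, ...) {
  cat(sprintf("<set_coexpression_result> observed = %.4f, null = %.4f +/- %.4f, Z = %.2f, p(%s) = %.4g [n = %d]\n",
              x$observed, x$null_mean, x$null_sd,
              if (is.na(x$z_score)) NA else x$z_score, x$tail, x$p_empirical,
              x$n_resamples))
  invisible(x)
}

#' Set co-expression test (observed median versus resampling null)
#'
#' Convenience wrapper: computes the observed within- or between-set median
#' correlation, draws the matching resampling null, and summarizes it as a
#' Z-score and an empirical p-value.
#'
#' @inheritParams median_set_coexpression
#' @inheritParams resampled_null
#' @inheritParams summarize_null
#' @param background Background gene population to resample from; defaults
#'   to all genes in `R`.
#' @return A `set_coexpression_result` with the null vector attached as
#'   element `null_medians`.
#' @export
set_coexpression_test <- function(R, set_a, set_b = NULL, background = rownames(R),
                                  n_resamples = 10000, seed = NULL,
                                  tail = "upper") {
  obs <- median_set_coexpression(R, set_a, set_b)
  nulls <- resampled_null(R, length(unique(set_a)),
                          if (!is.null(set_b)) length(unique(set_b)),
                          background, n_resamples, seed)
  res <- summarize_null(obs, nulls, tail)
  res$null_medians <- nulls
  res
}
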