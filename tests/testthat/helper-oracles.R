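# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation.

# Expression matrix from explicit values with generated ids.
toy_expr <- function(values) {
  values <- as.matrix(values)
  rownames(values) <- paste0("g", seq_len(nrow(values)))
  colnames(values) <- paste0("s", seq_len(ncol(values)))
  expression_matrix(values)
}

# Correlation matrix object built directly from a symmetric matrix.
toy_cor <- function(M, ids = paste0("g", seq_len(nrow(M)))) {
  dimnames(M) <- list(ids, ids)
  structure(M, zero_variance = character(0),
            class = c("correlation_matrix", "matrix"))
}

# Watts-Strogatz local clustering by explicit neighbor-pair counting.
brute_local_clustering <- function(adj, i) {
  nb <- which(adj[i, ] != 0)
  k <- length(nb)
  if (k < 2) return(NA_real_)
  pairs <- utils::combn(nb, 2)
  links <- sum(adj[cbind(pairs[1, ], pairs[2, ])] != 0)
  2 * links / (k * (k - 1))
}

# Step-up BH by direct evaluation of the definition:
# adjusted(i) = min_{j >= i} p_(j) * m / j, capped at 1, in input order.
brute_bh <- function(p, m = length(p)) {
  o <- order(p)
  ps <- p[o]
  adj <- sapply(seq_along(ps), function(i)
    min(1, min(ps[i:length(ps)] * m / (i:length(ps)))))
  out <- numeric(length(p))
  out[o] <- adj
  out
}

# Median within-set correlation by exhaustive pair listing.
brute_median_within <- function(M, idx) {
  pairs <- utils::combn(idx, 2)
  stats::median(M[cbind(pairs[1, ], pairs[2, ])])
}

# Exact binomial central 99% acceptance interval for a count at rate p0.
binom99 <- function(n, p0 = 0.05) {
  c(stats::qbinom(0.005, n, p0), stats::qbinom(0.995, n, p0))
}
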