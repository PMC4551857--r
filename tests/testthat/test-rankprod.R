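# Matrices of exp(log-values) so the log2 fold-change chain is exercised.
rp_expr <- function(logvals, prefix) {
  m <- exp(as.matrix(logvals))
  dimnames(m) <- list(paste0("g", seq_len(nrow(m))),
                      paste0(prefix, seq_len(ncol(m))))
  m
}

test_that("rank products are geometric means of fold-change ranks with average ties", {
  # 3 genes, 1 case and 2 control replicates -> 2 comparisons;
  # case chosen so up-ranks are g1:(1,2), g2:(2,1), g3:(3,3)
  control <- rp_expr(cbind(c(0, 0, 0), c(-3, -5, 0)), "c")
  case <- rp_expr(cbind(c(4, 3, -1)), "t")
  rp <- rank_product(case, control)
  expect_equal(rp$rp_up, c(sqrt(2), sqrt(2), 3))

  # unanimity: ranked 1 in every comparison gives the minimum rp = 1
  case2 <- rp_expr(cbind(c(9, 0, -1)), "t")
  expect_equal(rank_product(case2, control)$rp_up[1], 1)

  # identical fold changes share an average rank
  control3 <- rp_expr(cbind(c(0, 0, 0)), "c")
  case3 <- rp_expr(cbind(c(2, 2, 1)), "t")
  rp3 <- rank_product(case3, control3)
  expect_equal(rp3$rp_up[1:2], c(1.5, 1.5))

  expect_error(rank_product(case, control[1:2, ]), "universe")
})

test_that("up-regulation ranks equal down-regulation ranks of the flipped contrast", {
  set.seed(23)
  case <- rp_expr(matrix(rnorm(60), 20), "t")
  control <- rp_expr(matrix(rnorm(60), 20), "c")
  expect_equal(rank_product(case, control)$rp_up,
               rank_product(control, case)$rp_down)
})

test_that("permutation p-values approach the exhaustive rank-configuration null", {
  # 3 genes x 1-vs-2 replicates: the null ranks each comparison independently;
  # enumerate all (3!)^2 = 36 configurations for the exact rp distribution
  control <- rp_expr(cbind(c(0, 0, 0), c(-1, 1, 0.5)), "c")
  case <- rp_expr(cbind(c(2, 1, 0)), "t")
  rp <- rank_product(case, control)
  perms <- as.matrix(expand.grid(1:6, 1:6))
  all_orders <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  exact_rps <- apply(perms, 1, function(ix) {
    r1 <- all_orders[ix[1], ]; r2 <- all_orders[ix[2], ]
    sqrt(r1 * r2)
  })  # 3 genes x 36 configurations
  exact_p <- sapply(rp$rp_up, function(x) mean(exact_rps <= x))
  est <- permutation_pvalues(rp$rp_up, case, control, +1,
                             n_permutations = 4000, seed = 11)
  # both estimators target #{null rp <= observed} / total
  expect_lt(max(abs(est$p - exact_p)), 0.02)
  expect_identical(est,
                   permutation_pvalues(rp$rp_up, case, control, +1, 4000, seed = 11))
})

test_that("the minimum attainable rank product earns the smallest p-value", {
  set.seed(31)
  case <- rp_expr(matrix(rnorm(40 * 2) + c(rep(4, 2), rep(0, 78)), 40), "t")
  control <- rp_expr(matrix(rnorm(40 * 2), 40), "c")
  rp <- rank_product(case, control)
  res <- permutation_pvalues(rp$rp_up, case, control, +1, 200, seed = 6)
  expect_equal(which.min(res$p), which.min(rp$rp_up))
  expect_true(all(res$pfp >= 0))
})

test_that("planted up-regulated genes are recovered by the top rank products", {
  rec <- sapply(1:10, function(s) {
    de <- generate_de_experiment(de_study_config(seed = s, n_genes = 2000))
    rp <- rank_product(de$case, de$control)
    top <- rp$gene[order(rp$rp_up)][seq_along(de$truth)]
    mean(top %in% de$truth)
  })
  expect_gte(median(rec), 0.8)
})
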