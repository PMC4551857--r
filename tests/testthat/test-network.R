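test_that("threshold graphs use a strict, signed cutoff", {
  M <- toy_cor(rbind(c(1, 0.95, 0.80, -0.95),
                     c(0.95, 1, 0.90, 0.2),
                     c(0.80, 0.90, 1, 0.1),
                     c(-0.95, 0.2, 0.1, 1)),
               ids = c("a", "b", "c", "d"))
  g <- build_threshold_graph(M, 0.9)
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 1)                       # only a-b: 0.95 > 0.9
  expect_setequal(as.vector(el), c("a", "b"))     # 0.90 exactly is excluded
  expect_equal(igraph::E(g)$correlation, 0.95)
  # negative correlations excluded under signed mode, included under absolute
  g_abs <- build_threshold_graph(M, 0.9, absolute = TRUE)
  expect_equal(igraph::ecount(g_abs), 2)
  expect_error(build_threshold_graph(M, 1.2), "threshold")
  # empty result is a graph, not an error
  expect_equal(igraph::ecount(build_threshold_graph(M, 0.99)), 0)
})

test_that("scopes keep within-set versus incident edges", {
  M <- toy_cor(matrix(0.95, 4, 4), ids = c("a", "b", "c", "d"))
  diag(M) <- 1
  gw <- build_threshold_graph(M, 0.9, focal_set = c("a", "b"), scope = "within_set")
  expect_equal(igraph::ecount(gw), 1)
  gi <- build_threshold_graph(M, 0.9, focal_set = c("a", "b"), scope = "incident")
  expect_equal(igraph::ecount(gi), 5)             # all but c-d
})

test_that("local clustering matches closed-form cases and brute-force counting", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  expect_equal(local_clustering(tri, "a"), 1)

  star <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3")
  expect_equal(local_clustering(star, "hub"), 0)
  expect_true(is.na(local_clustering(star, "l1")))   # degree 1: undefined
  expect_error(local_clustering(star, "zz"), "zz")

  # 4-cycle A-B-C-D with chord A-C
  g <- igraph::graph_from_edgelist(rbind(c("A","B"), c("B","C"), c("C","D"),
                                         c("D","A"), c("A","C")), directed = FALSE)
  expect_equal(local_clustering(g, "A"), 2/3)
  expect_equal(local_clustering(g, "B"), 1)
  expect_equal(mean_clustering(g), 5/6)

  # random 20-node graphs against the brute-force triangle-counting oracle
  set.seed(13)
  for (rep in 1:5) {
    adj <- matrix(rbinom(400, 1, 0.2), 20)
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
    diag(adj) <- 0
    dimnames(adj) <- list(paste0("n", 1:20), paste0("n", 1:20))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    for (v in igraph::V(g)$name)
      expect_equal(local_clustering(g, v), brute_local_clustering(adj, v))
  }
})

test_that("degree-preserving nulls keep the degree sequence exactly and reproduce rigid graphs", {
  tri <- igraph::make_full_graph(3)
  res <- degree_preserving_null(tri, n_networks = 20, seed = 1)
  expect_equal(res$ratio, 1)
  expect_equal(res$p_empirical, 1)

  set.seed(3)
  g <- igraph::sample_gnp(30, 0.15)
  obs_deg <- sort(igraph::degree(g))
  for (i in 1:10) {
    gn <- neurocoex:::.rewire_preserving_degrees(g)
    expect_identical(sort(igraph::degree(gn)), obs_deg)
    expect_equal(igraph::ecount(gn), igraph::ecount(g))
    expect_false(igraph::any_multiple(gn) || any(igraph::which_loop(gn)))
  }
})

test_that("Erdos-Renyi graphs show no excess clustering against the rewiring null", {
  set.seed(29)
  g <- igraph::sample_gnp(50, 0.1)
  res <- degree_preserving_null(g, n_networks = 200, seed = 30)
  expect_gt(res$ratio, 0.8)
  expect_lt(res$ratio, 1.25)
})

test_that("mean clustering is invariant to node relabelling", {
  set.seed(17)
  g <- igraph::sample_gnp(25, 0.2)
  igraph::V(g)$name <- paste0("v", 1:25)
  perm <- sample(25)
  g2 <- igraph::permute(g, perm)
  expect_equal(mean_clustering(g), mean_clustering(g2))
})

test_that("edge counts shrink monotonically as the threshold rises", {
  set.seed(19)
  R <- correlation_matrix(toy_expr(matrix(rnorm(40 * 12), 40)))
  counts <- sapply(seq(0.1, 0.9, by = 0.1), function(th)
    igraph::ecount(build_threshold_graph(R, th)))
  expect_true(all(diff(counts) <= 0))
})

test_that("threshold sweep agrees with a single null run and reports empty cutoffs as absent", {
  gen <- generate_module_matrix(synthetic_config(
    n_genes = 120, n_samples = 50,
    modules = list(list(size = 30, rho = 0.9)),
    set_labels = list(IS = 1:30), seed = 21))
  R <- correlation_matrix(gen$expr)
  sw <- threshold_sweep(R, c(0.6, 0.99), gen$sets$IS, n_networks = 50, seed = 5)
  one <- degree_preserving_null(build_threshold_graph(R, 0.6, gen$sets$IS),
                                n_networks = 50, seed = 5 + 1)
  expect_equal(sw$ratio[1], one$ratio)
  expect_equal(sw$p[1], one$p_empirical)
  expect_true(is.na(sw$ratio[2]) && sw$n_edges[2] == 0)   # empty graph: absent
})

test_that("edge-composition chi-square matches the closed form and rejects degenerate partitions", {
  # 6 focal + 5 other nodes: expected fraction (6-1)/(11-1) = 0.5;
  # complete focal clique (15 within) + 5 focal-other edges = 20 incident
  focal <- paste0("f", 1:6); other <- paste0("o", 1:5)
  el <- rbind(t(combn(focal, 2)), cbind(focal[1:5], other))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$in_focal <- igraph::V(g)$name %in% focal
  res <- edge_composition_test(g)
  expect_equal(res$n_incident, 20)
  expect_equal(res$n_within, 15)
  expect_equal(res$expected_fraction, 0.5)
  expect_equal(res$chi_square, 5)                  # (15-10)^2/10 + (5-10)^2/10
  expect_equal(res$p_value, pchisq(5, 1, lower.tail = FALSE))

  # all-focal graph is degenerate
  g3 <- igraph::make_full_graph(4)
  igraph::V(g3)$in_focal <- TRUE
  expect_error(edge_composition_test(g3), "degenerate")
})
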