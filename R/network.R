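#' Build a thresholded co-expression graph
#'
#' Nodes are genes, edges connect pairs whose correlation strictly exceeds
#' the threshold (`R > t`; "above" is strict, so a pair at exactly the
#' threshold is excluded). By default only positive correlations qualify;
#' `absolute = TRUE` thresholds `|R|` instead. Undefined correlations
#' (zero-variance genes) never form edges. Isolated nodes are dropped.
#'
#' @param R A [correlation_matrix()].
#' @param threshold Cutoff in (0, 1).
#' @param focal_set Optional character vector of focal genes (e.g. the
#'   immune-system set). With `scope = "within_set"` only focal-focal edges
#'   are kept; with `scope = "incident"` every edge with at least one focal
#'   endpoint is kept.
#' @param scope `"within_set"` (default) or `"incident"`; ignored when
#'   `focal_set` is `NULL` (all edges kept).
#' @param absolute Logical; threshold on `|R|` rather than signed `R`.
#' @return An `igraph` object with vertex attribute `in_focal` (logical),
#'   edge attribute `correlation`, and graph attributes `threshold` and
#'   `scope`. May be empty (zero vertices) if no edge survives.
#' @export
build_threshold_graph <- function(R, threshold, focal_set = NULL,
                                  scope = c("within_set", "incident"),
                                  absolute = FALSE) {
  scope <- match.arg(scope)
  if (!(threshold > 0 && threshold < 1)) stop("threshold must lie in (0, 1)")
  Rm <- unclass(R)
  vals <- if (absolute) abs(Rm) else Rm
  A <- !is.na(vals) & vals > threshold
  diag(A) <- FALSE
  if (!is.null(focal_set)) {
    focal <- rownames(Rm) %in% focal_set
    if (scope == "within_set") {
      A <- A & outer(focal, focal, `&`)
    } else {
      A <- A & outer(focal, focal, `|`)
    }
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$in_focal <- if (is.null(focal_set)) TRUE else rownames(Rm) %in% focal_set
  igraph::E(g)$correlation <- Rm[igraph::as_edgelist(g)]
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  igraph::set_graph_attr(g, "scope", if (is.null(focal_set)) "all" else scope)
}

#' Local clustering coefficient of a node
#'
#' The Watts-Strogatz index: the fraction of realized edges among all
#' possible edges between the node's immediate neighbors,
#' `C = 2 e_N / (k (k - 1))` for degree `k >= 2`. Nodes of degree < 2 have no
#' neighbor pair and return `NA` ("undefined"); they are excluded from mean
#' clustering coefficients.
#'
#' @param g An `igraph` graph.
#' @param node Vertex name (or index).
#' @return Clustering coefficient in \[0, 1\], or `NA` for degree < 2.
#' @export
local_clustering <- function(g, node) {
  if (is.character(node) && !(node %in% igraph::V(g)$name))
    stop("node not present in graph: ", node)
  c_ <- unname(igraph::transitivity(g, type = "local", vids = node, isolates = "NaN"))
  ifelse(is.nan(c_), NA_real_, c_)
}

#' Mean local clustering coefficient
#'
#' Mean of [local_clustering()] over all nodes of degree >= 2 (nodes with an
#' undefined coefficient are excluded rather than scored 0).
#'
#' @param g An `igraph` graph.
#' @return Scalar mean, or `NA` if no node has degree >= 2.
#' @export
mean_clustering <- function(g) {
  c_ <- igraph::transitivity(g, type = "local", isolates = "NaN")
  c_ <- c_[!is.nan(c_)]
  if (length(c_) == 0) return(NA_real_)
  mean(c_)
}

# One degree-preserving rewiring of g: repeated double-edge swaps that
# reject self-loops and multi-edges; swap attempts >= 10x edge count.
.rewire_preserving_degrees <- function(g, swap_factor = 10) {
  igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                           niter = swap_factor * igraph::ecount(g)))
}

#' Degree-preserving clustering null
#'
#' Compares the observed mean clustering coefficient against an ensemble of
#' networks with identical node count, edge count and degree sequence,
#' generated by double-edge-swap rewiring of the observed graph (at least
#' 10 swap attempts per edge; swaps creating self-loops or parallel edges
#' are rejected). The degree sequence of every null draw is asserted to
#' equal the observed one. Graphs that admit no valid swap (e.g. a single
#' triangle) reproduce themselves: ratio 1, p 1.
#'
#' @param g An `igraph` graph with at least one edge.
#' @param n_networks Number of null networks (the reference analyses use
#'   10,000).
#' @param seed Integer seed.
#' @param swap_factor Swap attempts per edge (default 10).
#' @return A `clustering_null_result` list: `observed_mean_C`, `null_means`,
#'   `null_mean_C`, `ratio` (observed over mean of null means),
#'   `p_empirical` (upper-tail, add-one), `n_networks`, `n_nodes`, `n_edges`.
#' @export
degree_preserving_null <- function(g, n_networks = 1000, seed = NULL,
                                   swap_factor = 10) {
  if (igraph::ecount(g) < 1) stop("graph has no edges")
  obs_deg <- sort(igraph::degree(g))
  obs_c <- mean_clustering(g)
  null_means <- with_seed(seed, {
    vapply(seq_len(n_networks), function(i) {
      gn <- .rewire_preserving_degrees(g, swap_factor)
      stopifnot(identical(sort(igraph::degree(gn)), obs_deg))
      mean_clustering(gn)
    }, numeric(1))
  })
  mu <- mean(null_means, na.rm = TRUE)
  p <- (1 + sum(null_means >= obs_c, na.rm = TRUE)) / (1 + length(null_means))
  structure(list(observed_mean_C = obs_c, null_means = null_means,
                 null_mean_C = mu,
                 ratio = if (is.na(mu) || mu == 0) NA_real_ else obs_c / mu,
                 p_empirical = p, n_networks = n_networks,
                 n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g)),
            class = "clustering_null_result")
}

#' @export
print.clustering_null_result <- function(x, ...) {
  cat(sprintf("<clustering_null_result> C = %.4f vs null %.4f (ratio %.2f), p = %.4g [%d nodes, %d edges, %d nulls]\n",
              x$observed_mean_C, x$null_mean_C, x$ratio, x$p_empirical,
              x$n_nodes, x$n_edges, x$n_networks))
  invisible(x)
}

#' Clustering ratio across a range of correlation thresholds
#'
#' For each threshold, builds the thresholded graph and runs
#' [degree_preserving_null()]. Thresholds at which the graph is empty are
#' reported with `NA` statistics (the graph is "absent" at that cutoff).
#'
#' @inheritParams build_threshold_graph
#' @inheritParams degree_preserving_null
#' @param thresholds Ascending numeric vector of cutoffs in (0, 1).
#' @return Data frame with one row per threshold: `threshold`, `n_nodes`,
#'   `n_edges`, `observed_C`, `null_mean_C`, `ratio`, `p`.
#' @export
threshold_sweep <- function(R, thresholds, focal_set = NULL,
                            scope = "within_set", n_networks = 1000,
                            seed = NULL, absolute = FALSE) {
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  rows <- lapply(seq_along(thresholds), function(i) {
    th <- thresholds[i]
    g <- build_threshold_graph(R, th, focal_set, scope, absolute)
    if (igraph::ecount(g) == 0)
      return(data.frame(threshold = th, n_nodes = 0L, n_edges = 0L,
                        observed_C = NA_real_, null_mean_C = NA_real_,
                        ratio = NA_real_, p = NA_real_))
    res <- degree_preserving_null(g, n_networks,
                                  seed = if (is.null(seed)) NULL else seed + i)
    data.frame(threshold = th, n_nodes = res$n_nodes, n_edges = res$n_edges,
               observed_C = res$observed_mean_C, null_mean_C = res$null_mean_C,
               ratio = res$ratio, p = res$p_empirical)
  })
  do.call(rbind, rows)
}

#' Chi-square test on the composition of edges incident to a focal set
#'
#' Among the edges with at least one endpoint in the focal set, tests
#' whether the proportion with both endpoints in the set exceeds the
#' proportion expected if a focal node chose its partner uniformly among the
#' other nodes of the graph: `expected_fraction = (n_focal - 1)/(n - 1)`.
#' One-degree-of-freedom chi-square over the two cells (within-set,
#' cross-set), no continuity correction.
#'
#' @param g An `igraph` graph, typically built with `scope = "incident"`;
#'   vertex attribute `in_focal` marks the focal set.
#' @return An `edge_composition_result` list: `n_within`, `n_incident`,
#'   `expected_fraction`, `chi_square`, `p_value`.
#' @export
edge_composition_test <- function(g) {
  focal <- igraph::V(g)$in_focal
  if (is.null(focal)) stop("graph carries no `in_focal` vertex attribute")
  el <- igraph::as_edgelist(g, names = FALSE)
  inc <- focal[el[, 1]] | focal[el[, 2]]
  n_incident <- sum(inc)
  if (n_incident == 0) stop("no edges incident to the focal set")
  n_within <- sum(focal[el[, 1]] & focal[el[, 2]])
  n_focal <- sum(focal); n_nodes <- igraph::vcount(g)
  expected_fraction <- (n_focal - 1) / (n_nodes - 1)
  exp_within <- n_incident * expected_fraction
  exp_cross <- n_incident * (1 - expected_fraction)
  if (exp_within == 0 || exp_cross == 0)
    stop("degenerate partition: an expected cell count is zero")
  chi <- (n_within - exp_within)^2 / exp_within +
    ((n_incident - n_within) - exp_cross)^2 / exp_cross
  structure(list(n_within = n_within, n_incident = n_incident,
                 expected_fraction = expected_fraction, chi_square = chi,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE)),
            class = "edge_composition_result")
}

#' @export
print.edge_composition_result <- function(x, ...) {
  cat(sprintf("<edge_composition_result> %d/%d within-set edges (expected fraction %.3f), X^2 = %.3f, p = %.4g\n",
              x$n_within, x$n_incident, x$expected_fraction, x$chi_square, x$p_value))
  invisible(x)
}

#' Write a graph as an edge-list TSV
#'
#' Columns: `node1`, `node2`, `correlation`.
#'
#' @param g An `igraph` graph with edge attribute `correlation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g)
  df <- data.frame(node1 = el[, 1], node2 = el[, 2],
                   correlation = igraph::E(g)$correlation,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
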