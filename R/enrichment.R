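#' Count hit-list genes annotated to a category
#'
#' @param hit_list Character vector of gene identifiers; must be contained
#'   in the annotation background.
#' @param annot An [annotation_table()].
#' @param category Category identifier (a column of the incidence matrix).
#' @return Integer count.
#' @export
count_annotated <- function(hit_list, annot, category) {
  if (!category %in% colnames(annot$incidence))
    stop("unknown category: ", category)
  hit_list <- unique(as.character(hit_list))
  outside <- setdiff(hit_list, annot$background)
  if (length(outside))
    stop("hit-list gene(s) outside annotation background: ",
         paste(utils::head(outside, 5), collapse = ", "))
  sum(annot$incidence[hit_list, category])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: sort ascending, `adjusted(i) = min over j >= i of
#' p(j) * m / j`, capped at 1, returned in the input order. `m` may exceed
#' the number of p-values supplied, reproducing adjustment "against" a fixed
#' number of tests (e.g. 21 subcategories) when only some are reported.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m Number of tests to adjust against; defaults to `length(p)` and
#'   must be at least that.
#' @return Adjusted p-values, same order as `p`.
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("m must be >= length(p)")
  stats::p.adjust(p, method = "BH", n = m)
}

#' Monte Carlo gene-set enrichment against a fixed background
#'
#' For each category, contrasts the number of hit-list genes annotated to it
#' with the count distribution over `n_resamples` random gene lists of the
#' same size drawn uniformly without replacement from the background. The
#' empirical p-value is upper-tail with the add-one correction (so the
#' smallest reportable p is `1/(n_resamples + 1)`, never 0); adjusted
#' p-values apply Benjamini-Hochberg across `m` tests.
#'
#' @param hit_list Non-empty character vector of genes within the background.
#' @param annot An [annotation_table()].
#' @param categories Category identifiers to test; defaults to every column
#'   of the incidence matrix.
#' @param n_resamples Number of random draws (>= 1000; reference analyses
#'   use at least 10,000).
#' @param m Number of tests for the BH adjustment; defaults to
#'   `length(categories)`.
#' @param seed Integer seed.
#' @return Data frame with one row per category: `category`,
#'   `category_name`, `observed_genes`, `expected_genes`, `sd_null`,
#'   `p_numeric`, `p_adjusted`.
#' @export
mc_enrichment <- function(hit_list, annot, categories = colnames(annot$incidence),
                          n_resamples = 10000, m = length(categories),
                          seed = NULL) {
  if (length(hit_list) == 0) stop("hit list is empty")
  if (n_resamples < 1000) stop("n_resamples must be >= 1000")
  hit_list <- unique(as.character(hit_list))
  observed <- vapply(categories, function(cc) count_annotated(hit_list, annot, cc),
                     numeric(1))
  inc <- annot$incidence[, categories, drop = FALSE]
  storage.mode(inc) <- "double"
  n_bg <- length(annot$background)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      colSums(inc[sample.int(n_bg, length(hit_list)), , drop = FALSE])
    }, numeric(length(categories)))
  })
  if (length(categories) == 1L) null_counts <- matrix(null_counts, nrow = 1)
  expected <- rowMeans(null_counts)
  sd_null <- apply(null_counts, 1, stats::sd)
  p_num <- (1 + rowSums(null_counts >= observed)) / (1 + n_resamples)
  nms <- if (!is.null(annot$category_names))
    unname(annot$category_names[categories]) else categories
  data.frame(category = categories, category_name = nms,
             observed_genes = observed, expected_genes = expected,
             sd_null = sd_null, p_numeric = p_num,
             p_adjusted = bh_adjust(p_num, m),
             row.names = NULL, stringsAsFactors = FALSE)
}
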