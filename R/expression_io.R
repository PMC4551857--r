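#' Construct an expression matrix
#'
#' Thin S3 wrapper around a numeric genes-by-samples matrix. Row names are
#' gene identifiers, column names are sample identifiers; both must be unique
#' and the matrix must be complete (no `NA`). Raw intensities are expected to
#' be non-negative; transformed values are unrestricted.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   row and column names set.
#' @param normalized Logical; whether per-sample total normalization has been
#'   applied (see [normalize_total_signal()]).
#' @return An object of class `expression_matrix` (a named numeric matrix
#'   with a `normalized` attribute).
#' @export
expression_matrix <- function(values, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values))
    stop("expression matrix contains missing values; missing values are rejected, not imputed")
  structure(values, normalized = isTRUE(normalized), class = c("expression_matrix", "matrix"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples%s\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "normalized"))) ", total-signal normalized" else ""))
  invisible(x)
}

#' Test for the expression_matrix class
#' @param x Object.
#' @return Logical scalar.
#' @export
is_expression_matrix <- function(x) inherits(x, "expression_matrix")

#' Read a tab-separated expression matrix
#'
#' Expected layout: a header row of sample identifiers, first column holding
#' probe or gene identifiers, remaining columns numeric. Missing values are
#' rejected at load.
#'
#' @param path Path to a TSV file.
#' @param normalized Logical flag recorded on the returned object.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, normalized = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs an identifier column plus >=1 sample column: ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  expression_matrix(m, normalized = normalized)
}

#' Write an expression matrix as TSV
#'
#' @param x An [expression_matrix()] or named numeric matrix.
#' @param path Output path.
#' @param id_column Name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path, id_column = "gene_id") {
  df <- data.frame(rownames(x), unclass(x), check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' Two-column TSV: probe identifier, comma-separated list of target gene
#' identifiers. Every probe must appear exactly once.
#'
#' @param path Path to a TSV file (header row required: probe, genes).
#' @return A `probe_map`: data frame with character column `probe_id` and
#'   list column `gene_ids`.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("probe map TSV needs two columns (probe, genes): ", path)
  probe_map(df[[1]], strsplit(as.character(df[[2]]), ",", fixed = TRUE))
}

#' Construct a probe map
#'
#' @param probe_ids Character vector of probe identifiers (unique).
#' @param gene_ids List of character vectors, one per probe: the gene(s) the
#'   probe matches.
#' @return A `probe_map` data frame.
#' @export
probe_map <- function(probe_ids, gene_ids) {
  probe_ids <- as.character(probe_ids)
  if (anyDuplicated(probe_ids))
    stop("probe map lists a probe more than once: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  gene_ids <- lapply(gene_ids, function(g) trimws(as.character(g)))
  if (length(gene_ids) != length(probe_ids)) stop("probe_ids and gene_ids lengths differ")
  structure(data.frame(probe_id = probe_ids, stringsAsFactors = FALSE),
            gene_ids = gene_ids, class = c("probe_map", "data.frame"))
}

#' Summarize probe-level expression to gene level
#'
#' Probes matching more than one gene are excluded outright; each remaining
#' gene's profile is the arithmetic mean of its probes' rows. Genes left with
#' no probe after the multi-mapping exclusion are absent from the output.
#'
#' @param probe_matrix Numeric probe-by-sample matrix with probe row names,
#'   or an [expression_matrix()].
#' @param map A [probe_map()] covering every probe row.
#' @return An [expression_matrix()] of gene-level means.
#' @export
summarize_probes <- function(probe_matrix, map) {
  if (!inherits(map, "probe_map")) stop("`map` must be a probe_map")
  probes <- rownames(probe_matrix)
  if (is.null(probes)) stop("probe matrix must carry probe row names")
  genes_per_probe <- attr(map, "gene_ids")
  names(genes_per_probe) <- map$probe_id
  missing <- setdiff(probes, map$probe_id)
  if (length(missing))
    stop("probe(s) absent from probe map: ", paste(missing, collapse = ", "))
  targets <- genes_per_probe[probes]
  keep <- lengths(targets) == 1L
  if (!any(keep)) stop("no probe maps to exactly one gene; nothing to summarize")
  m <- unclass(probe_matrix)[keep, , drop = FALSE]
  gene <- unlist(targets[keep], use.names = FALSE)
  sums <- rowsum(m, group = gene)
  counts <- as.vector(table(gene)[rownames(sums)])
  expression_matrix(sums / counts)
}

#' Remove probes that fall below the negative-control signal everywhere
#'
#' A probe is dropped iff its value is strictly below the per-sample mean of
#' the negative-control probes in every sample; probes equal to the control
#' mean in some sample are retained. The negative-control rows themselves are
#' removed from the output.
#'
#' @param probe_matrix Numeric probe-by-sample matrix with probe row names.
#' @param negative_control_ids Identifiers of the negative-control rows;
#'   must be non-empty and present in the matrix.
#' @return The filtered matrix (same class as the input values).
#' @export
filter_below_negative_controls <- function(probe_matrix, negative_control_ids) {
  probes <- rownames(probe_matrix)
  negative_control_ids <- as.character(negative_control_ids)
  if (length(negative_control_ids) == 0L) stop("no negative controls supplied")
  if (!all(negative_control_ids %in% probes))
    stop("negative control(s) not found in matrix: ",
         paste(setdiff(negative_control_ids, probes), collapse = ", "))
  m <- unclass(probe_matrix)
  ctrl_mean <- colMeans(m[negative_control_ids, , drop = FALSE])
  rest <- m[setdiff(probes, negative_control_ids), , drop = FALSE]
  below_everywhere <- rowSums(sweep(rest, 2, ctrl_mean, `<`)) == ncol(rest)
  rest[!below_everywhere, , drop = FALSE]
}

#' Normalize each sample against its total signal
#'
#' Divides each sample column by its own total so that column sums equal 1.
#' Idempotent; columns with zero or negative totals are an error.
#'
#' @param x An [expression_matrix()] or named numeric matrix.
#' @return An [expression_matrix()] with the `normalized` flag set.
#' @export
normalize_total_signal <- function(x) {
  m <- unclass(x)
  totals <- colSums(m)
  bad <- totals <= 0
  if (any(bad))
    stop("sample(s) with non-positive total signal: ",
         paste(colnames(m)[bad], collapse = ", "))
  expression_matrix(sweep(m, 2, totals, `/`), normalized = TRUE)
}
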