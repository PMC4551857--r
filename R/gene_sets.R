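#' Gene set collections
#'
#' A named list of gene-identifier sets over a background universe. Every set
#' must be a subset of the background; within-set duplicates are collapsed.
#'
#' @param sets Named list of character vectors.
#' @param background Character vector: the universe of genes under study.
#' @return A `gene_set_collection` (named list with a `background` attribute).
#' @export
gene_set_collection <- function(sets, background) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set must be named")
  background <- unique(as.character(background))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  for (nm in names(sets)) {
    extra <- setdiff(sets[[nm]], background)
    if (length(extra))
      stop("set '", nm, "' contains gene(s) outside the background: ",
           paste(utils::head(extra, 5), collapse = ", "))
  }
  structure(sets, background = background, class = "gene_set_collection")
}

#' Remove shared genes from a pair of sets
#'
#' Genes annotated to both sets are dropped from both, so downstream
#' within-set versus between-set comparisons are not inflated by shared
#' members. Genes outside the intersection are untouched.
#'
#' @param set_a,set_b Character vectors of gene identifiers.
#' @return List with elements `a` and `b`, the disjoint sets, plus `shared`,
#'   the removed intersection.
#' @export
enforce_disjoint <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  shared <- intersect(set_a, set_b)
  list(a = setdiff(set_a, shared), b = setdiff(set_b, shared), shared = shared)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (set name, description, then member genes,
#'   tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions;
#'   defaults to the set names.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  if (is.null(names(sets))) stop("gene sets must be named")
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- ontology ----------------------------------------------------------

#' Construct an ontology from is_a edges
#'
#' @param terms Character vector of term identifiers.
#' @param parents Named list mapping each term to its direct `is_a` parents
#'   (terms with no parents may be omitted).
#' @param names Optional named character vector of human-readable term names.
#' @return An `ontology` object.
#' @export
ontology <- function(terms, parents = list(), names = NULL) {
  terms <- unique(as.character(terms))
  parents <- lapply(parents, as.character)
  unknown <- setdiff(names(parents), terms)
  if (length(unknown)) stop("parent list refers to unknown term(s): ",
                            paste(unknown, collapse = ", "))
  structure(list(terms = terms, parents = parents, term_names = names),
            class = "ontology")
}

#' Read term identifiers and is_a links from an OBO file
#'
#' Minimal OBO flat-file reader: `[Term]` stanzas with `id:`, `name:` and
#' `is_a:` tags. Optionally treats `relationship: part_of` as a parent link.
#'
#' @param path Path to an OBO file.
#' @param include_part_of Logical; also follow `part_of` relationships
#'   (default `FALSE`: only `is_a` is propagated).
#' @return An [ontology()].
#' @export
read_obo <- function(path, include_part_of = FALSE) {
  lines <- readLines(path, warn = FALSE)
  terms <- character(); term_names <- character(); parents <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && nzchar(cur$id)) {
      terms[[length(terms) + 1L]] <<- cur$id
      term_names[[cur$id]] <<- cur$name
      if (length(cur$parents)) parents[[cur$id]] <<- cur$parents
    }
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)  # strip trailing comments
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(id = "", name = "", parents = character()) }
    else if (grepl("^\\[", ln)) { flush(); cur <- NULL }  # [Typedef] etc.
    else if (!is.null(cur)) {
      if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
      else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
      else if (startsWith(ln, "is_a:"))
        cur$parents <- c(cur$parents, trimws(sub("^is_a:", "", ln)))
      else if (include_part_of && grepl("^relationship:\\s*part_of\\s", ln))
        cur$parents <- c(cur$parents, trimws(sub("^relationship:\\s*part_of", "", ln)))
      else if (ln == "is_obsolete: true") cur$id <- ""
    }
  }
  flush()
  parents <- lapply(parents, function(p) intersect(p, terms))
  ontology(terms, parents, names = unlist(term_names)[terms])
}

#' Ancestors of a term under is_a closure
#'
#' @param ont An [ontology()].
#' @param term Term identifier.
#' @return Character vector of ancestor term identifiers (excluding `term`).
#' @export
term_ancestors <- function(ont, term) {
  seen <- character()
  frontier <- ont$parents[[term]]
  while (length(frontier)) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(ont$parents[frontier], use.names = FALSE))
  }
  seen
}

# Kahn peeling on the child->parent graph; returns NULL if acyclic, else one
# cycle as a term vector (closed: first element repeated at the end).
.find_cycle <- function(ont) {
  n_parents <- setNames(integer(length(ont$terms)), ont$terms)
  n_parents[names(ont$parents)] <- lengths(ont$parents)
  children <- split(rep(names(ont$parents), lengths(ont$parents)),
                    factor(unlist(ont$parents, use.names = FALSE), levels = ont$terms))
  queue <- ont$terms[n_parents == 0L]   # roots first
  removed <- 0L
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]; removed <- removed + 1L
    for (ch in children[[t]]) {
      n_parents[ch] <- n_parents[ch] - 1L
      if (n_parents[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (removed == length(ont$terms)) return(NULL)
  residual <- ont$terms[n_parents > 0L]
  path <- residual[[1]]
  repeat {
    nxt <- intersect(ont$parents[[path[length(path)]]], residual)[1]
    if (nxt %in% path) return(c(path[which(path == nxt):length(path)], nxt))
    path <- c(path, nxt)
  }
}

# ---- annotation tables -------------------------------------------------

#' Construct an annotation table
#'
#' Gene-by-category incidence over a fixed background universe.
#'
#' @param background Character vector: the gene universe (size N).
#' @param annotations Data frame with columns `gene` and `category` (long
#'   format), or a logical incidence matrix with gene row names and category
#'   column names.
#' @param category_names Optional named character vector mapping category
#'   identifiers to human-readable names.
#' @return An `annotation_table`: list with `background`, logical `incidence`
#'   matrix (background genes x categories) and `category_names`.
#' @export
annotation_table <- function(background, annotations, category_names = NULL) {
  background <- unique(as.character(background))
  if (is.matrix(annotations)) {
    extra <- setdiff(rownames(annotations), background)
    if (length(extra)) stop("annotated gene(s) outside background: ",
                            paste(utils::head(extra, 5), collapse = ", "))
    inc <- matrix(FALSE, length(background), ncol(annotations),
                  dimnames = list(background, colnames(annotations)))
    inc[rownames(annotations), colnames(annotations)] <- annotations != 0
  } else {
    g <- as.character(annotations$gene)
    cat_ <- as.character(annotations$category)
    extra <- setdiff(g, background)
    if (length(extra)) stop("annotated gene(s) outside background: ",
                            paste(utils::head(extra, 5), collapse = ", "))
    cats <- unique(cat_)
    inc <- matrix(FALSE, length(background), length(cats),
                  dimnames = list(background, cats))
    inc[cbind(g, cat_)] <- TRUE
  }
  structure(list(background = background, incidence = inc,
                 category_names = category_names),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("<annotation_table> %d background genes x %d categories\n",
              length(x$background), ncol(x$incidence)))
  invisible(x)
}

#' Read a long-format annotation TSV
#'
#' @param path TSV with header and columns `gene`, `category` (a third
#'   column `category_name` is used for display names when present).
#' @param background Gene universe; defaults to the genes present in the file.
#' @return An [annotation_table()].
#' @export
read_annotation_tsv <- function(path, background = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("gene", "category") %in% names(df)))
    stop("annotation TSV must have 'gene' and 'category' columns: ", path)
  if (is.null(background)) background <- unique(df$gene)
  nms <- NULL
  if ("category_name" %in% names(df)) {
    u <- !duplicated(df$category)
    nms <- setNames(df$category_name[u], df$category[u])
  }
  annotation_table(background, df[c("gene", "category")], category_names = nms)
}

#' Write an annotation table as long-format TSV
#'
#' @param annot An [annotation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annot, path) {
  idx <- which(annot$incidence, arr.ind = TRUE)
  df <- data.frame(gene = rownames(annot$incidence)[idx[, 1]],
                   category = colnames(annot$incidence)[idx[, 2]],
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene, df$category), ]
  if (!is.null(annot$category_names))
    df$category_name <- unname(annot$category_names[df$category])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Propagate annotations from child terms to their ancestors
#'
#' Every gene annotated to a term becomes annotated to all `is_a` ancestors
#' of that term that appear in the table; membership is recorded at most
#' once per term regardless of the number of paths. Idempotent.
#'
#' @param annot An [annotation_table()].
#' @param ont An [ontology()]; must be acyclic.
#' @return The propagated [annotation_table()].
#' @export
propagate_annotations <- function(annot, ont) {
  cyc <- .find_cycle(ont)
  if (!is.null(cyc))
    stop("ontology is_a graph contains a cycle: ", paste(cyc, collapse = " -> "))
  inc <- annot$incidence
  cats <- colnames(inc)
  for (term in intersect(cats, ont$terms)) {
    anc <- intersect(term_ancestors(ont, term), cats)
    if (length(anc))
      inc[, anc] <- inc[, anc, drop = FALSE] | inc[, term]
  }
  annotation_table(annot$background, inc, category_names = annot$category_names)
}

#' Bundled annotation table: TNF-alpha-responsive immune-system genes
#'
#' A curated 31-gene annotation table for rat genes significantly
#' up-regulated in cultured neonatal superior-cervical-ganglion neurons after
#' 24 h of TNF-alpha stimulation, with membership marks for six immune-system
#' GO categories (immune system process, immune response, leukocyte
#' migration, regulation of immune system process, positive regulation of
#' immune system process, activation of immune response). Ships with the
#' package as a plain-text fixture and serves as the worked example for the
#' enrichment counting routines.
#'
#' @return An [annotation_table()] whose background is the 31 genes.
#' @export
load_tnf_is_annotations <- function() {
  path <- system.file("extdata", "tnf_upregulated_is_genes.tsv",
                      package = "neurocoex", mustWork = TRUE)
  read_annotation_tsv(path)
}
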