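#' Run the full co-expression analysis pipeline from a single config
#'
#' Stages (each can be toggled): `simulate` (or load a matrix and gene sets
#' from files), `coexpr` (within-set and between-set median co-expression
#' versus resampling nulls), `network` (threshold graph, degree-preserving
#' clustering null, threshold sweep, edge-composition test), `rankprod`
#' (two-condition differential expression) and `enrich` (Monte Carlo
#' enrichment of the up-regulated list). Observed statistics depend only on
#' the data; the seed governs every null draw. Every output file is written
#' under `out_dir` and the machine-readable report records the config hash
#' and seed.
#'
#' @param config A named list, or path to a YAML/JSON file with the same
#'   structure. Recognized top-level fields: `seed`; `simulate` (logical or
#'   a list overriding [module_study_config()] / [de_study_config()]
#'   arguments); `matrix`, `sets` (paths, used when `simulate` is false);
#'   `coexpr` (`n_resamples`, `tail`), `network` (`threshold`, `thresholds`,
#'   `n_networks`, `scope`), `rankprod` (`n_permutations`), `enrich`
#'   (`n_resamples`, `m`, `annotation` path); each stage entry may be
#'   `NULL`/absent to skip it.
#' @param out_dir Output directory (created if needed).
#' @return The report, invisibly: a nested list also written as
#'   `report.json` in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, null = "null", digits = NA)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  report <- list(config_hash = unname(tools::md5sum(cfg_path)), seed = seed,
                 stages = list())
  t0 <- Sys.time()
  say <- function(stage) message(sprintf("[neurocoex +%.1fs] %s",
                                         as.numeric(Sys.time() - t0, units = "secs"), stage))

  run_stage <- function(name, fn) {
    say(paste("stage:", name))
    res <- tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    report$stages[[name]] <<- res
    res
  }

  # ---- inputs ----------------------------------------------------------
  sim <- !is.null(config$simulate) && !identical(config$simulate, FALSE)
  if (sim) {
    sim_args <- if (is.list(config$simulate)) config$simulate else list()
    mod_cfg <- do.call(module_study_config,
                       c(list(seed = seed),
                         sim_args[intersect(names(sim_args), c("n_genes", "n_samples"))]))
    gen <- generate_module_matrix(mod_cfg)
    expr <- gen$expr; sets <- gen$sets
    write_expression_tsv(expr, file.path(out_dir, "matrix.tsv"))
    write_gmt(sets, file.path(out_dir, "sets.gmt"))
    jsonlite::write_json(gen$truth, file.path(out_dir, "truth_modules.json"))
  } else {
    if (is.null(config$matrix)) stop("config needs either simulate: true or a matrix path")
    expr <- read_expression_tsv(config$matrix, normalized = TRUE)
    sets <- if (!is.null(config$sets)) read_gmt(config$sets) else list()
  }

  R <- NULL
  need_R <- !is.null(config$coexpr) || !is.null(config$network)
  if (need_R) {
    say("correlation matrix")
    R <- correlation_matrix(expr)
  }
  set_a <- if (length(sets) >= 1) sets[[1]] else NULL
  set_b <- if (length(sets) >= 2) sets[[2]] else NULL
  if (!is.null(set_a) && !is.null(set_b)) {
    disj <- enforce_disjoint(set_a, set_b)
    set_a <- disj$a; set_b <- disj$b
  }

  # ---- coexpr ----------------------------------------------------------
  if (!is.null(config$coexpr) && !is.null(set_a)) {
    run_stage("coexpr", function() {
      nr <- config$coexpr$n_resamples %||% 10000
      tail <- config$coexpr$tail %||% "upper"
      within <- set_coexpression_test(R, set_a, background = rownames(R),
                                      n_resamples = nr, seed = seed, tail = tail)
      out <- list(within = within[c("observed", "null_mean", "null_sd",
                                    "z_score", "p_empirical", "n_resamples")])
      if (!is.null(set_b)) {
        between <- set_coexpression_test(R, set_a, set_b, rownames(R),
                                         n_resamples = nr, seed = seed + 1L, tail = tail)
        out$between <- between[c("observed", "null_mean", "null_sd",
                                 "z_score", "p_empirical", "n_resamples")]
      }
      out
    })
  }

  # ---- network ---------------------------------------------------------
  if (!is.null(config$network) && !is.null(set_a)) {
    run_stage("network", function() {
      th <- config$network$threshold %||% 0.9
      nn <- config$network$n_networks %||% 10000
      scope <- config$network$scope %||% "within_set"
      g <- build_threshold_graph(R, th, set_a, scope)
      out <- list(threshold = th, n_nodes = igraph::vcount(g),
                  n_edges = igraph::ecount(g))
      if (igraph::ecount(g) > 0) {
        write_edge_list(g, file.path(out_dir, "network_edges.tsv"))
        null_res <- degree_preserving_null(g, nn, seed = seed + 2L)
        out$clustering <- null_res[c("observed_mean_C", "null_mean_C",
                                     "ratio", "p_empirical", "n_networks")]
      }
      gi <- build_threshold_graph(R, th, set_a, "incident")
      if (igraph::ecount(gi) > 0 &&
          !all(igraph::V(gi)$in_focal) && any(igraph::V(gi)$in_focal)) {
        ec <- edge_composition_test(gi)
        out$edge_composition <- ec[c("n_within", "n_incident",
                                     "expected_fraction", "chi_square", "p_value")]
      }
      if (!is.null(config$network$thresholds)) {
        sweep_df <- threshold_sweep(R, config$network$thresholds, set_a,
                                    scope, n_networks = nn, seed = seed + 3L)
        utils::write.table(sweep_df, file.path(out_dir, "threshold_sweep.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out$sweep <- sweep_df
      }
      out
    })
  }

  # ---- rankprod / enrich ----------------------------------------------
  de_list <- NULL
  if (!is.null(config$rankprod)) {
    run_stage("rankprod", function() {
      if (sim) {
        sim_args <- if (is.list(config$simulate)) config$simulate else list()
        de_cfg <- de_study_config(seed = seed,
                                  n_genes = sim_args$n_genes %||% 2000)
        de <- generate_de_experiment(de_cfg)
        case <- de$case; control <- de$control
        jsonlite::write_json(de$truth, file.path(out_dir, "truth_de.json"))
      } else {
        case <- read_expression_tsv(config$rankprod$case)
        control <- read_expression_tsv(config$rankprod$control)
      }
      np <- config$rankprod$n_permutations %||% 100
      res <- rank_product_test(case, control, n_permutations = np, seed = seed + 4L)
      utils::write.table(res, file.path(out_dir, "rankprod.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      de_list <<- res$gene[res$p_up < 0.05]
      list(n_genes = nrow(res), n_up_p05 = length(de_list),
           n_down_p05 = sum(res$p_down < 0.05))
    })
  }
  if (!is.null(config$enrich)) {
    run_stage("enrich", function() {
      annot <- if (!is.null(config$enrich$annotation))
        read_annotation_tsv(config$enrich$annotation,
                            background = config$enrich$background)
      else load_tnf_is_annotations()
      hits <- if (!is.null(de_list)) intersect(de_list, annot$background)
              else annot$background
      if (length(hits) == 0) hits <- annot$background
      nr <- config$enrich$n_resamples %||% 10000
      res <- mc_enrichment(hits, annot, n_resamples = nr,
                           m = config$enrich$m %||% ncol(annot$incidence),
                           seed = seed + 5L)
      utils::write.table(res, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res
    })
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", force = TRUE)
  say("done")
  invisible(report)
}

#' Read a pipeline configuration file
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
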