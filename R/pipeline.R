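#' Pipeline configuration
#'
#' Collects stage toggles, thresholds, keyword list, input paths, seed and
#' output directory for [run_pipeline()]. The configuration round-trips
#' losslessly through JSON ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' Exactly one input route must be active: `use_table1` (the packaged
#' panel fixture, selection only), `matrix_path` + `groups_path` (an
#' on-disk experiment), or `simulate` (a [sim_config()] specification).
#'
#' @param out_dir output directory (created if absent).
#' @param use_table1 run selection on the packaged fixture.
#' @param matrix_path,groups_path expression matrix TSV and its sample
#'   group companion.
#' @param simulate `NULL`, or a list of [sim_config()] arguments plus
#'   optional `n_planted`, `planted_fold`, `decoy_rate`.
#' @param normalize quantile-normalize the input matrix before contrasts.
#' @param select run the two-tier selection (default `TRUE`).
#' @param integrate run the target-integration stage; requires target,
#'   gene-DE and GO inputs (paths, or a simulation).
#' @param targets_path,gene_de_path,go_path integration input TSVs.
#' @param fold_cut,fold_cut_single,alpha threshold parameters, see
#'   [thresholds()].
#' @param keywords GO keyword list (default [default_go_keywords()]).
#' @param seed integer seed for any stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            use_table1 = FALSE,
                            matrix_path = NULL, groups_path = NULL,
                            simulate = NULL,
                            normalize = FALSE, select = TRUE,
                            integrate = FALSE,
                            targets_path = NULL, gene_de_path = NULL,
                            go_path = NULL,
                            fold_cut = 5, fold_cut_single = 10, alpha = 0.05,
                            keywords = default_go_keywords(),
                            seed = 1L) {
  routes <- c(use_table1, !is.null(matrix_path), !is.null(simulate))
  if (sum(routes) != 1L)
    stop("exactly one input route required: use_table1, matrix_path, or simulate")
  for (p in c(matrix_path, groups_path, targets_path, gene_de_path, go_path))
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  structure(list(out_dir = out_dir, use_table1 = use_table1,
                 matrix_path = matrix_path, groups_path = groups_path,
                 simulate = simulate, normalize = normalize, select = select,
                 integrate = integrate, targets_path = targets_path,
                 gene_de_path = gene_de_path, go_path = go_path,
                 fold_cut = fold_cut, fold_cut_single = fold_cut_single,
                 alpha = alpha, keywords = keywords, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`; `path` a JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$keywords <- as.character(x$keywords)
  do.call(pipeline_config, x)
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
}

#' Run the full profiling pipeline
#'
#' Executes the configured stages in fixed order — input (fixture, file, or
#' simulation), optional normalization, differential expression, two-tier
#' selection, target integration — and writes a result bundle to
#' `config$out_dir`: `selection.tsv`, `summary.json`, `pairs.tsv` and
#' network files when integrating, and `run.log` recording the thresholds
#' actually applied. Identical configuration (and seed) gives identical
#' outputs; any stage failure removes partial outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the selection table, summary, and (when
#'   applicable) pair records and ground truth.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  out_file <- function(name) {
    p <- file.path(config$out_dir, name)
    written <<- c(written, p)
    p
  }
  log_con <- file(out_file("run.log"), open = "wt")
  ok <- FALSE
  on.exit({
    close(log_con)
    if (!ok) unlink(written)
  })

  thr <- thresholds(fold_cut = config$fold_cut,
                    fold_cut_single = config$fold_cut_single,
                    alpha = config$alpha)
  log_line(log_con, sprintf(
    "thresholds: |fold| > %g (call), |fold| >= %g (single line), p_adj < %g",
    thr$fold_cut, thr$fold_cut_single, thr$alpha))

  stage <- "input"
  result <- tryCatch({
    truth <- NULL; sim_res <- NULL
    if (config$use_table1) {
      log_line(log_con, "input: packaged 46-miRNA panel fixture")
      calls <- table1_long()
      mir_de <- calls
    } else {
      if (!is.null(config$simulate)) {
        log_line(log_con, "input: simulation, seed ", config$seed)
        sc_args <- config$simulate
        n_planted <- sc_args$n_planted %||% 0
        planted_fold <- sc_args$planted_fold %||% 10
        decoy_rate <- sc_args$decoy_rate %||% 0.5
        sc_args[c("n_planted", "planted_fold", "decoy_rate")] <- NULL
        sc_args$seed <- config$seed
        cfg <- do.call(sim_config, sc_args)
        if (n_planted > 0)
          cfg <- do.call(sim_config, c(sc_args, list(
            planted_effects = plant_signature_effects(n_planted, planted_fold,
                                                      cfg))))
        sim <- simulate_expression(cfg)
        em <- sim$matrix; truth <- sim$truth
        if (config$integrate) {
          stage <- "simulate_resources"
          sim_res <- simulate_target_resources(truth, cfg,
                                               decoy_rate = decoy_rate,
                                               fold_cut = thr$fold_cut)
          truth <- sim_res$truth
        }
      } else {
        log_line(log_con, "input: ", config$matrix_path)
        em <- read_expression_matrix(config$matrix_path, config$groups_path)
      }
      if (config$normalize) {
        stage <- "normalize"
        em <- expr_matrix(quantile_normalize(em), groups(em))
        log_line(log_con, "quantile normalization applied")
      }
      stage <- "diffexpr"
      de <- run_all_contrasts(em)
      write_contrast_tsv(de, out_file("contrasts.tsv"))
      mir_de <- contrasts_to_calls(de)
      calls <- mir_de
    }

    selection <- NULL; summary <- list()
    if (config$select) {
      stage <- "select"
      line_drugs <- default_line_drugs()
      present <- unique(as.character(calls$cell_line))
      if (!all(present %in% names(line_drugs)))
        line_drugs <- stats::setNames(
          rep(c("CIS", "PAC"), length.out = length(present)), sort(present))
      selection <- apply_two_tier_selection(calls, thr, line_drugs)
      ct <- build_call_table(calls, thr)
      summary <- selection_summary(selection, ct, line_drugs)
      utils::write.table(selection, out_file("selection.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      log_line(log_con, "selected ", summary$n_selected, " miRNA(s)")
    }

    pairs <- NULL
    if (config$integrate) {
      stage <- "integrate"
      if (!is.null(sim_res)) {
        db <- sim_res$db; gene_de <- sim_res$gene_de; go <- sim_res$go
      } else {
        if (is.null(config$targets_path) || is.null(config$gene_de_path) ||
            is.null(config$go_path))
          stop("integrate needs targets_path, gene_de_path, go_path")
        db <- aggregate_targets(read_target_edges(config$targets_path))
        gene_de <- read_contrast_tsv(config$gene_de_path)
        go <- read_go_annotations(config$go_path)
      }
      sel_mirs <- if (!is.null(selection))
        selection$mirna[selection$selected] else unique(mir_de$mirna)
      pairs <- select_inverse_pairs(mir_de[mir_de$mirna %in% sel_mirs, ],
                                    gene_de, db, thr)
      pairs <- filter_by_go(pairs, go, config$keywords)
      write_pairs(pairs, out_file("pairs.tsv"))
      for (ln in unique(as.character(pairs$cell_line))) {
        sub <- pairs[pairs$cell_line == ln, ]
        export_network(sub, out_file(paste0("network_", ln, ".sif")), "sif")
        export_network(sub, out_file(paste0("network_", ln, ".graphml")),
                       "graphml")
      }
      summary$n_pairs <- nrow(pairs)
      log_line(log_con, "retained ", nrow(pairs), " miRNA-target pair(s)")
    }

    jsonlite::write_json(summary, out_file("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(selection = selection, summary = summary, pairs = pairs,
         truth = truth)
  }, error = function(e) {
    stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
         call. = FALSE)
  })
  ok <- TRUE
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
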