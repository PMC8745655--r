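#' Simulation configuration
#'
#' Describes a synthetic miRNA array experiment: the five-group panel (one
#' parental reference plus four drug-resistant lines), replicate count,
#' feature universe, planted signed fold changes, and i.i.d. Gaussian
#' log2-scale noise. Defaults mirror the study design: 4 replicates per
#' group, five A2780-derived groups with the parental line first (the
#' reference), and a noise standard deviation of 0.25 log2 units, a typical
#' replicate-level spread for single-channel miRNA arrays (the source data
#' report none, so this is a package choice).
#'
#' @param n_features number of miRNA features (the real chip holds 2578
#'   mature miRNAs; tests default to a few hundred for speed).
#' @param n_replicates samples per group (default 4).
#' @param groups ordered group identifiers; the first is the reference.
#' @param planted_effects data.frame (`feature`, `group`, `fold`) of planted
#'   signed folds, `|fold| >= 1`; or `NULL` for a null simulation. See
#'   [plant_signature_effects()].
#' @param noise_sd Gaussian noise sd in log2 units (default 0.25).
#' @param baseline_mean baseline log2 intensity (default 7).
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_features = 200, n_replicates = 4,
                       groups = c("A2780", "A2780CR1", "A2780CR2",
                                  "A2780PR1", "A2780PR2"),
                       planted_effects = NULL, noise_sd = 0.25,
                       baseline_mean = 7, seed = 1L) {
  if (n_features < 1 || n_replicates < 1) stop("sizes must be positive")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (anyDuplicated(groups) || length(groups) < 2)
    stop("groups must be >= 2 distinct identifiers")
  if (!is.null(planted_effects)) {
    stopifnot(all(c("feature", "group", "fold") %in% names(planted_effects)))
    if (any(abs(planted_effects$fold) < 1))
      stop("planted signed folds must satisfy |fold| >= 1")
    bad <- setdiff(planted_effects$group, groups[-1])
    if (length(bad))
      stop("planted effects reference unknown or reference group: ",
           paste(unique(bad), collapse = ", "))
  }
  structure(list(n_features = as.integer(n_features),
                 n_replicates = as.integer(n_replicates),
                 groups = groups, planted_effects = planted_effects,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Plant a resistance-signature effect design
#'
#' Deterministic helper building a `planted_effects` table that mirrors the
#' biology the selection rule targets: each planted miRNA is perturbed in
#' \emph{both} cell lines resistant to one drug (alternating between the
#' two drug pairs), with the sign alternating up/down.
#'
#' @param n_planted number of planted miRNAs.
#' @param fold fold magnitude (default 10).
#' @param config a [sim_config()] supplying feature universe and groups.
#' @return data.frame (`feature`, `group`, `fold`).
#' @export
plant_signature_effects <- function(n_planted, fold = 10,
                                    config = sim_config()) {
  if (n_planted > config$n_features)
    stop("cannot plant more features than the universe holds")
  features <- feature_names(config)[seq_len(n_planted)]
  lines <- config$groups[-1]
  if (length(lines) %% 2L != 0L)
    stop("signature design expects an even number of resistant lines")
  pairs <- split(lines, rep(seq_len(length(lines) / 2), each = 2))
  rows <- lapply(seq_len(n_planted), function(i) {
    pair <- pairs[[(i - 1L) %% length(pairs) + 1L]]
    f <- if (i %% 2L == 0L) -abs(fold) else abs(fold)
    data.frame(feature = features[i], group = pair, fold = f)
  })
  do.call(rbind, rows)
}

feature_names <- function(config)
  sprintf("mir%04d", seq_len(config$n_features))

#' Simulate an expression matrix with known ground truth
#'
#' Every entry is `baseline_mean` plus, for planted (feature, group)
#' combinations, `sign(fold) * log2(|fold|)`, plus i.i.d. Gaussian noise of
#' sd `noise_sd`. Identical configuration (including seed) gives
#' bit-identical output.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (an [expr_matrix()]) and `truth` (class
#'   `ground_truth`: `de_features` data.frame, plus empty
#'   `target_edges_true` / `go_labels` slots filled by
#'   [simulate_target_resources()]).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  features <- feature_names(config)
  samples <- paste(rep(config$groups, each = config$n_replicates),
                   sprintf("r%d", seq_len(config$n_replicates)), sep = "_")
  grp <- rep(config$groups, each = config$n_replicates)
  mu <- matrix(config$baseline_mean, config$n_features, length(samples),
               dimnames = list(features, samples))
  pe <- config$planted_effects
  if (!is.null(pe)) {
    for (i in seq_len(nrow(pe))) {
      shift <- sign(pe$fold[i]) * log2(abs(pe$fold[i]))
      mu[pe$feature[i], grp == pe$group[i]] <-
        config$baseline_mean + shift
    }
  }
  noise <- matrix(stats::rnorm(length(mu), sd = config$noise_sd),
                  nrow(mu), ncol(mu))
  truth <- structure(
    list(de_features = if (is.null(pe))
           data.frame(feature = character(), group = character(),
                      fold = numeric())
         else pe,
         target_edges_true = data.frame(mirna = character(),
                                        gene = character()),
         go_labels = list()),
    class = "ground_truth")
  list(matrix = expr_matrix(mu + noise, grp), truth = truth)
}

#' Simulate target database, mRNA DE table, and GO annotations
#'
#' Builds the integration-stage inputs implied by a simulated truth: one
#' target gene per planted miRNA, whose mRNA signed fold is opposite in
#' sign to the miRNA's planted fold (magnitude drawn above the cut-off)
#' in the cell lines where the miRNA was planted, and near 1 elsewhere.
#' Decoy edges are added at `decoy_rate` per planted edge, split between
#' same-sign targets (defeating the inverse filter) and sub-threshold
#' targets (defeating the cut-off filter), so the two filters are
#' separately falsifiable. Every planted gene — and every decoy gene, so
#' the GO stage is not what rejects decoys — receives one of the six
#' default GO keywords.
#'
#' @param truth `ground_truth` from [simulate_expression()] with at least
#'   one planted effect.
#' @param config the generating [sim_config()].
#' @param decoy_rate expected decoy edges per planted edge (default 0.5).
#' @param fold_cut the cut-off the true target folds must clear
#'   (default 5).
#' @return list: `db` (a `target_db`), `gene_de` (long data.frame `gene`,
#'   `cell_line`, `fold`, `p_adj`), `go` (data.frame `gene`, `term`), and
#'   `truth` updated with `target_edges_true` and `go_labels`.
#' @export
simulate_target_resources <- function(truth, config, decoy_rate = 0.5,
                                      fold_cut = 5) {
  stopifnot(inherits(truth, "ground_truth"))
  pe <- truth$de_features
  if (nrow(pe) == 0L) stop("truth contains no planted effects")
  set.seed(config$seed + 1L)  # distinct stream from the expression draw
  lines <- config$groups[-1]
  mirnas <- unique(pe$feature)
  gene_of <- stats::setNames(paste0("GENE_", toupper(mirnas)), mirnas)
  preds <- target_sources()$predicted
  vals <- target_sources()$validated
  kw <- default_go_keywords()

  gene_rows <- list(); edge_rows <- list(); go_rows <- list()
  rand_mag <- function(n) 2^stats::runif(n, log2(fold_cut * 1.2),
                                         log2(fold_cut * 8))
  for (i in seq_along(mirnas)) {
    m <- mirnas[i]; g <- gene_of[[m]]
    planted_lines <- pe[pe$feature == m, ]
    for (ln in lines) {
      hit <- match(ln, planted_lines$group)
      if (!is.na(hit)) {
        fold <- -sign(planted_lines$fold[hit]) * rand_mag(1)
        p <- stats::runif(1, 1e-8, 1e-4)
      } else {
        fold <- signed_fold(stats::runif(1, -0.4, 0.4))
        p <- stats::runif(1, 0.2, 0.95)
      }
      gene_rows[[length(gene_rows) + 1L]] <-
        data.frame(gene = g, cell_line = ln, fold = fold, p_adj = p)
    }
    src <- sample(c(preds, vals), sample(1:3, 1))
    edge_rows[[length(edge_rows) + 1L]] <-
      data.frame(mirna = m, gene = g, source = src)
    go_rows[[length(go_rows) + 1L]] <-
      data.frame(gene = g, term = kw[(i - 1L) %% length(kw) + 1L])
  }

  # decoys: half same-sign (inverse filter must reject), half sub-threshold
  n_decoy <- round(decoy_rate * length(mirnas))
  if (n_decoy > 0) {
    decoy_mirs <- sample(mirnas, n_decoy, replace = TRUE)
    for (j in seq_len(n_decoy)) {
      m <- decoy_mirs[j]
      same_sign <- j %% 2L == 1L
      g <- sprintf("DECOY_%s_%03d", if (same_sign) "SAME" else "SUB", j)
      planted_lines <- pe[pe$feature == m, ]
      for (ln in lines) {
        hit <- match(ln, planted_lines$group)
        if (!is.na(hit)) {
          if (same_sign) {
            fold <- sign(planted_lines$fold[hit]) * rand_mag(1)
            p <- stats::runif(1, 1e-8, 1e-4)
          } else {
            fold <- -sign(planted_lines$fold[hit]) *
              2^stats::runif(1, 0.1, log2(fold_cut * 0.9))
            p <- stats::runif(1, 1e-8, 1e-4)
          }
        } else {
          fold <- signed_fold(stats::runif(1, -0.4, 0.4))
          p <- stats::runif(1, 0.2, 0.95)
        }
        gene_rows[[length(gene_rows) + 1L]] <-
          data.frame(gene = g, cell_line = ln, fold = fold, p_adj = p)
      }
      edge_rows[[length(edge_rows) + 1L]] <-
        data.frame(mirna = m, gene = g, source = sample(c(preds, vals), 1))
      go_rows[[length(go_rows) + 1L]] <-
        data.frame(gene = g, term = kw[j %% length(kw) + 1L])
    }
  }

  edges <- do.call(rbind, edge_rows)
  db <- aggregate_targets(split(edges[c("mirna", "gene")], edges$source))
  gene_de <- do.call(rbind, gene_rows)
  go <- unique(do.call(rbind, go_rows))
  truth$target_edges_true <- data.frame(mirna = mirnas,
                                        gene = unname(gene_of[mirnas]))
  truth$go_labels <- split(as.character(go$term), go$gene)
  list(db = db, gene_de = gene_de, go = go, truth = truth)
}

#' Recovery metrics against a simulation's ground truth
#'
#' @param selected output of [apply_two_tier_selection()], or a character
#'   vector of selected miRNA names.
#' @param pairs pair records from the integration stage (may be `NULL` to
#'   skip pair-level metrics).
#' @param truth `ground_truth` for the same simulation.
#' @return list: `sensitivity` and `fdp` for miRNA selection, per-tier
#'   counts among true positives, and (when `pairs` given)
#'   `pair_sensitivity` / `pair_fdp`.
#' @export
evaluate_recovery <- function(selected, pairs = NULL, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.data.frame(selected)) {
    sel_tab <- selected[selected$selected, , drop = FALSE]
    sel <- as.character(sel_tab$mirna)
    tiers <- table(factor(sel_tab$tier[sel_tab$mirna %in%
                                         truth$de_features$feature],
                          levels = c("two-line-same-drug",
                                     "single-line-10x", "both")))
  } else {
    sel <- as.character(selected)
    tiers <- NULL
  }
  true_mirs <- unique(as.character(truth$de_features$feature))
  tp <- intersect(sel, true_mirs)
  out <- list(
    sensitivity = if (length(true_mirs)) length(tp) / length(true_mirs) else NA_real_,
    fdp = length(setdiff(sel, true_mirs)) / max(1L, length(sel)),
    tier_counts = tiers)
  if (!is.null(pairs)) {
    key <- function(d) paste(d$mirna, d$gene, sep = "\r")
    got <- unique(key(pairs))
    want <- unique(key(truth$target_edges_true))
    out$pair_sensitivity <- if (length(want)) length(intersect(got, want)) / length(want) else NA_real_
    out$pair_fdp <- length(setdiff(got, want)) / max(1L, length(got))
  }
  out
}
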