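#' Selection thresholds
#'
#' Cut-offs for directional calling and the two-tier signature rule.
#' Defaults follow the study design: a call requires a signed fold strictly
#' beyond +/-5 with adjusted p strictly below 0.05; the single-line tier
#' requires at least a 10-fold change (non-strict, "at least 10-fold") with
#' the same significance.
#'
#' @param fold_cut fold magnitude for a directional call (default 5).
#' @param fold_cut_single fold magnitude for the single-line tier
#'   (default 10); must be `>= fold_cut`.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param strict_fold compare `|fold|` strictly (`>`) against `fold_cut`
#'   (default `TRUE`); the single-line tier always uses `>=`.
#' @param strict_alpha compare `p_adj` strictly (`<`) against `alpha`
#'   (default `TRUE`).
#' @return a `thresholds` list.
#' @export
thresholds <- function(fold_cut = 5, fold_cut_single = 10, alpha = 0.05,
                       strict_fold = TRUE, strict_alpha = TRUE) {
  if (fold_cut <= 1 || fold_cut_single <= 1) stop("fold cut-offs must exceed 1")
  if (fold_cut_single < fold_cut)
    stop("fold_cut_single must be >= fold_cut")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(fold_cut = fold_cut, fold_cut_single = fold_cut_single,
                 alpha = alpha, strict_fold = strict_fold,
                 strict_alpha = strict_alpha),
            class = "thresholds")
}

#' @export
print.thresholds <- function(x, ...) {
  cat(sprintf("call: |fold| %s %g and p_adj %s %g; single-line tier: |fold| >= %g\n",
              if (x$strict_fold) ">" else ">=", x$fold_cut,
              if (x$strict_alpha) "<" else "<=", x$alpha, x$fold_cut_single))
  invisible(x)
}

#' Default cell-line to drug map
#'
#' The study panel: two cisplatin-resistant (CR) and two paclitaxel-
#' resistant (PR) sublines of the parental A2780 line.
#'
#' @return named character vector, cell line -> drug.
#' @export
default_line_drugs <- function() {
  c(A2780CR1 = "CIS", A2780CR2 = "CIS", A2780PR1 = "PAC", A2780PR2 = "PAC")
}

sig_pass <- function(p_adj, thr) {
  if (thr$strict_alpha) p_adj < thr$alpha else p_adj <= thr$alpha
}

fold_pass <- function(fold, cut, strict) {
  if (strict) abs(fold) > cut else abs(fold) >= cut
}

#' Directional call for one (miRNA, cell line) result
#'
#' `up` when the signed fold exceeds the cut-off and the adjusted p passes;
#' `down` for the mirror case; `none` otherwise. Vectorized.
#'
#' @param fold signed fold change(s), `|fold| >= 1`.
#' @param p_adj adjusted p-value(s).
#' @param thr a [thresholds()] object.
#' @return factor with levels `up`, `down`, `none`.
#' @examples
#' call_direction(c(-29.12, 9.45, 5.0), c(3.61e-9, 0.0896, 0.01), thresholds())
#' @export
call_direction <- function(fold, p_adj, thr = thresholds()) {
  sig <- sig_pass(p_adj, thr)
  big <- fold_pass(fold, thr$fold_cut, thr$strict_fold)
  out <- ifelse(sig & big & fold > 0, "up",
                ifelse(sig & big & fold < 0, "down", "none"))
  factor(out, levels = c("up", "down", "none"))
}

#' Build the per-line call table
#'
#' @param calls data.frame with columns `mirna`, `cell_line`, `fold`,
#'   `p_adj` (one row per miRNA per resistant line); the long form emitted
#'   by [table1_long()] or assembled from [run_all_contrasts()] output.
#' @param thr a [thresholds()] object.
#' @return the input with a `call` factor column appended.
#' @export
build_call_table <- function(calls, thr = thresholds()) {
  need <- c("mirna", "cell_line", "fold", "p_adj")
  if (!all(need %in% names(calls)))
    stop("calls must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(calls[c("mirna", "cell_line")]))
    stop("duplicate (mirna, cell_line) rows")
  calls$call <- call_direction(calls$fold, calls$p_adj, thr)
  calls
}

#' Two-tier resistance-signature selection
#'
#' A miRNA enters the signature when either
#' \itemize{
#'   \item tier 1: it carries a significant directional call (|fold| beyond
#'     the call cut-off, p below alpha) in \emph{both} cell lines resistant
#'     to the same drug, or
#'   \item tier 2: it changes at least `fold_cut_single`-fold (default 10)
#'     with significance in at least one resistant line.
#' }
#' Both tiers can apply simultaneously.
#'
#' @param calls long data.frame (`mirna`, `cell_line`, `fold`, `p_adj`).
#' @param thr a [thresholds()] object.
#' @param line_drugs named vector mapping each cell line to its drug;
#'   default [default_line_drugs()]. Every cell line in `calls` must be
#'   mapped, and all mapped lines must be present.
#' @return data.frame, one row per miRNA: `mirna`, `selected`, `tier`
#'   (`two-line-same-drug`, `single-line-10x`, `both`, or `NA` when not
#'   selected), `category` (`up_only` / `down_only` / `mixed`, `NA` when no
#'   calls), `n_lines_changed`, and logical signature columns
#'   `<DRUG>_up` / `<DRUG>_down` per drug.
#' @examples
#' tab <- table1_long()
#' sel <- apply_two_tier_selection(tab)
#' table(sel$tier)
#' @export
apply_two_tier_selection <- function(calls, thr = thresholds(),
                                     line_drugs = default_line_drugs()) {
  lines_present <- unique(as.character(calls$cell_line))
  unmapped <- setdiff(lines_present, names(line_drugs))
  if (length(unmapped)) stop("cell line(s) not mapped to a drug: ",
                             paste(unmapped, collapse = ", "))
  missing <- setdiff(names(line_drugs), lines_present)
  if (length(missing)) stop("missing contrast for cell line(s): ",
                            paste(missing, collapse = ", "))
  ct <- build_call_table(calls, thr)
  ct$drug <- unname(line_drugs[as.character(ct$cell_line)])
  ct$tier2_hit <- fold_pass(ct$fold, thr$fold_cut_single, strict = FALSE) &
    sig_pass(ct$p_adj, thr)

  drugs <- unique(unname(line_drugs))
  per_mirna <- function(df) {
    changed <- df$call != "none"
    tier1 <- any(vapply(drugs, function(d) {
      sub <- df[df$drug == d, ]
      nrow(sub) >= 2L && all(sub$call != "none")
    }, logical(1)))
    tier2 <- any(df$tier2_hit)
    tier <- if (tier1 && tier2) "both"
            else if (tier1) "two-line-same-drug"
            else if (tier2) "single-line-10x"
            else NA_character_
    has_up <- any(df$call == "up"); has_down <- any(df$call == "down")
    category <- if (has_up && has_down) "mixed"
                else if (has_up) "up_only"
                else if (has_down) "down_only"
                else NA_character_
    sig <- unlist(lapply(drugs, function(d) {
      sub <- df[df$drug == d, ]
      stats::setNames(c(nrow(sub) >= 2L && all(sub$call == "up"),
                        nrow(sub) >= 2L && all(sub$call == "down")),
                      paste0(d, c("_up", "_down")))
    }))
    c(list(selected = tier1 || tier2, tier = tier, category = category,
           n_lines_changed = sum(changed)), as.list(sig))
  }

  mirnas <- unique(as.character(ct$mirna))
  rows <- lapply(mirnas, function(m) {
    as.data.frame(per_mirna(ct[ct$mirna == m, ]), stringsAsFactors = FALSE)
  })
  out <- cbind(mirna = mirnas, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Classify miRNAs by call pattern
#'
#' @param call_table output of [build_call_table()].
#' @return data.frame per miRNA: `category` (`up_only`, `down_only`,
#'   `mixed`, or `NA` when all calls are `none`) and `n_lines_changed`.
#' @export
classify_mirnas <- function(call_table) {
  sp <- split(call_table, call_table$mirna)
  out <- do.call(rbind, lapply(names(sp), function(m) {
    cl <- sp[[m]]$call
    has_up <- any(cl == "up"); has_down <- any(cl == "down")
    data.frame(mirna = m,
               category = if (has_up && has_down) "mixed"
                          else if (has_up) "up_only"
                          else if (has_down) "down_only"
                          else NA_character_,
               n_lines_changed = sum(cl != "none"))
  }))
  out <- out[match(unique(call_table$mirna), out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drug-specific signatures
#'
#' A miRNA is in drug D's up-signature when called `up` in both D-resistant
#' lines (down analogously). A miRNA may sit in both drugs' signatures with
#' opposite directions (the panel contains such cases).
#'
#' @param call_table output of [build_call_table()].
#' @param line_drugs named cell line -> drug map.
#' @return named list, one element per drug, each a list with `up` and
#'   `down` character vectors of miRNA names.
#' @export
drug_signatures <- function(call_table, line_drugs = default_line_drugs()) {
  call_table$drug <- unname(line_drugs[as.character(call_table$cell_line)])
  drugs <- unique(unname(line_drugs))
  out <- lapply(drugs, function(d) {
    sub <- call_table[call_table$drug == d, ]
    sp <- split(sub, sub$mirna)
    consistent <- function(dir)
      names(sp)[vapply(sp, function(x) nrow(x) >= 2L && all(x$call == dir),
                       logical(1))]
    list(up = sort(consistent("up")), down = sort(consistent("down")))
  })
  stats::setNames(out, drugs)
}

#' Summary counts of a selection
#'
#' The counts reported for a resistance-signature analysis: total selected,
#' category breakdown, number of miRNAs changed in each possible number of
#' lines, and the drug signatures.
#'
#' @param selection output of [apply_two_tier_selection()].
#' @param call_table output of [build_call_table()] on the same inputs.
#' @param line_drugs named cell line -> drug map.
#' @return list of counts and signature membership, JSON-serializable.
#' @export
selection_summary <- function(selection, call_table,
                              line_drugs = default_line_drugs()) {
  sel <- selection[selection$selected, ]
  n_lines <- length(unique(call_table$cell_line))
  per_k <- vapply(0:n_lines, function(k) sum(sel$n_lines_changed == k),
                  integer(1))
  names(per_k) <- paste0("changed_in_", 0:n_lines, "_lines")
  sigs <- drug_signatures(call_table, line_drugs)
  list(
    n_selected = nrow(sel),
    n_up_only = sum(sel$category == "up_only", na.rm = TRUE),
    n_down_only = sum(sel$category == "down_only", na.rm = TRUE),
    n_mixed = sum(sel$category == "mixed", na.rm = TRUE),
    per_k_lines = as.list(per_k),
    signatures = lapply(sigs, function(s) list(up = s$up, down = s$down))
  )
}
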