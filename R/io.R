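#' Load the packaged 46-miRNA resistance panel fixture
#'
#' The package ships the published per-line signed fold changes and
#' FDR-adjusted p-values for the 46 miRNAs retained by the two-tier
#' selection in the A2780 resistance panel (four resistant lines, each
#' contrasted against the parental line). Values are transcribed verbatim;
#' the file's checksum is verified on load.
#'
#' @return data.frame, 46 rows: `accession`, `mirna`, then `fold_<line>`
#'   and `padj_<line>` for each of A2780CR1, A2780CR2, A2780PR1, A2780PR2.
#' @examples
#' tab <- load_table1_fixture()
#' tab[tab$mirna == "hsa-miR-205-5p", c("fold_A2780PR1", "padj_A2780PR1")]
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_mirna_folds.csv", package = "mirsig",
                      mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, table1_md5))
    stop("fixture checksum mismatch: expected ", table1_md5, ", got ", md5)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) != 46L) stop("fixture must contain 46 rows")
  tab
}

# md5 of the shipped fixture; recorded at transcription time
table1_md5 <- "93b650f6d246fd1de2dd5d83c1650ed6"

#' Fixture in long call-input form
#'
#' Reshapes the wide fixture (or any table with `fold_<line>` /
#' `padj_<line>` columns) into the long (`mirna`, `cell_line`, `fold`,
#' `p_adj`) form the selection operations consume.
#'
#' @param tab wide table; default [load_table1_fixture()].
#' @return long data.frame.
#' @export
table1_long <- function(tab = load_table1_fixture()) {
  fold_cols <- grep("^fold_", names(tab), value = TRUE)
  lines <- sub("^fold_", "", fold_cols)
  out <- do.call(rbind, lapply(lines, function(ln) {
    data.frame(mirna = tab$mirna, cell_line = ln,
               fold = tab[[paste0("fold_", ln)]],
               p_adj = tab[[paste0("padj_", ln)]])
  }))
  rownames(out) <- NULL
  out
}

#' Contrast results in call-input form
#'
#' @param de output of [run_all_contrasts()] (or [run_contrast()] with a
#'   `cell_line` column).
#' @return data.frame (`mirna`, `cell_line`, `fold`, `p_adj`).
#' @export
contrasts_to_calls <- function(de) {
  data.frame(mirna = de$feature, cell_line = de$cell_line,
             fold = de$signed_fold, p_adj = de$p_adj)
}

#' Read / write an expression matrix
#'
#' TSV with a header row of sample identifiers and a first column of
#' feature identifiers; `read . write` is the identity on values and
#' ordering. Group labels travel in a companion two-column TSV
#' (`sample`, `group`).
#'
#' @param path matrix TSV path.
#' @param groups_path optional companion TSV; alternatively pass `groups`
#'   directly.
#' @param groups optional character vector of group labels.
#' @return an [expr_matrix()] (or a bare matrix when no groups are given).
#' @export
read_expression_matrix <- function(path, groups_path = NULL, groups = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature id: ", ids[duplicated(ids)][1])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in matrix body")
  rownames(m) <- ids
  if (!is.null(groups_path)) {
    g <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
    if (!all(c("sample", "group") %in% names(g)))
      stop("groups file needs columns `sample` and `group`")
    groups <- g$group[match(colnames(m), g$sample)]
    if (anyNA(groups)) stop("groups file does not cover all samples")
  }
  if (is.null(groups)) return(m)
  expr_matrix(m, groups)
}

#' @rdname read_expression_matrix
#' @param x matrix or `expr_matrix` to write.
#' @export
write_expression_matrix <- function(x, path, groups_path = NULL) {
  # %.17g keeps doubles bit-identical through the text round trip
  body <- apply(unclass(x), 2L, sprintf, fmt = "%.17g")
  df <- data.frame(feature = rownames(x), body, check.names = FALSE)
  colnames(df) <- c("feature", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    g <- data.frame(sample = colnames(x), group = as.character(groups(x)))
    utils::write.table(g, groups_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a per-contrast differential-expression table
#'
#' Fixed column layout shared by the selection stage and external
#' consumers: `feature`, `log2_diff`, `signed_fold`, `t_mod`, `p_raw`,
#' `p_adj` (plus `cell_line` for stacked tables).
#'
#' @param de contrast data.frame; `path` a TSV path.
#' @export
write_contrast_tsv <- function(de, path) {
  keep <- intersect(c("cell_line", "feature", "log2_diff", "signed_fold",
                      "t_mod", "p_raw", "p_adj"), names(de))
  utils::write.table(de[keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_contrast_tsv
#' @export
read_contrast_tsv <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)

#' Read miRNA-target edge tables
#'
#' TSV with columns `mirna`, `gene`, `source`; returns the named list of
#' per-source tables that [aggregate_targets()] consumes.
#'
#' @param path TSV path.
#' @return named list of data.frames.
#' @export
read_target_edges <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna", "gene", "source") %in% names(tab)))
    stop("target edge file needs columns mirna, gene, source")
  split(tab[c("mirna", "gene")], tab$source)
}

#' @rdname read_target_edges
#' @param db a `target_db` (long form written with one row per
#'   edge-source combination so the file round-trips).
#' @export
write_target_edges <- function(db, path) {
  srcs <- strsplit(db$sources, ",", fixed = TRUE)
  long <- data.frame(mirna = rep(db$mirna, lengths(srcs)),
                     gene = rep(db$gene, lengths(srcs)),
                     source = unlist(srcs))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write GO annotation tables
#'
#' Two-column TSV: `gene`, `term`.
#' @param path TSV path.
#' @export
read_go_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(tab)))
    stop("annotation file needs columns gene, term")
  tab
}

#' @rdname read_go_annotations
#' @param annotations data.frame (`gene`, `term`).
#' @export
write_go_annotations <- function(annotations, path) {
  utils::write.table(annotations[c("gene", "term")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write retained miRNA-target pair records
#'
#' TSV round-trip of the integration output: re-reading reproduces the
#' pair list exactly.
#'
#' @param pairs pair records; `path` a TSV path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("validated" %in% names(tab)) tab$validated <- as.logical(tab$validated)
  tab
}
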