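#' Recognized target-database sources
#'
#' Four prediction databases and two experimentally validated collections.
#'
#' @return list with `predicted` and `validated` character vectors.
#' @export
target_sources <- function() {
  list(predicted = c("DIANA", "Miranda", "PicTar", "TargetScan"),
       validated = c("miRTAR", "miRwalk"))
}

#' Aggregate miRNA-target edge tables into one database
#'
#' Union semantics: the same (miRNA, gene) edge contributed by several
#' sources becomes one edge whose provenance is the union of the sources.
#' An edge is flagged validated when any contributing source is an
#' experimentally validated collection.
#'
#' @param source_tables named list of data.frames, each with columns
#'   `mirna` and `gene`; names are the source names.
#' @param extra_sources optional character vector of additional accepted
#'   source names (treated as predicted).
#' @return `target_db` data.frame: `mirna`, `gene`, `sources`
#'   (comma-separated, sorted), `validated`. Rows with a missing miRNA or
#'   gene are dropped with a message reporting the count.
#' @examples
#' db <- aggregate_targets(list(
#'   TargetScan = data.frame(mirna = "miR-1", gene = "TIMP3"),
#'   miRwalk    = data.frame(mirna = "miR-1", gene = "TIMP3")))
#' db$validated  # TRUE
#' @export
aggregate_targets <- function(source_tables, extra_sources = character()) {
  known <- c(unlist(target_sources(), use.names = FALSE), extra_sources)
  bad <- setdiff(names(source_tables), known)
  if (is.null(names(source_tables)) || any(!nzchar(names(source_tables))))
    stop("source_tables must be a named list")
  if (length(bad)) stop("unrecognized source(s): ", paste(bad, collapse = ", "))
  long <- do.call(rbind, lapply(names(source_tables), function(src) {
    tab <- source_tables[[src]]
    if (!all(c("mirna", "gene") %in% names(tab)))
      stop("source ", src, " lacks mirna/gene columns")
    data.frame(mirna = as.character(tab$mirna),
               gene = as.character(tab$gene), source = src)
  }))
  ok <- !is.na(long$mirna) & nzchar(long$mirna) &
        !is.na(long$gene) & nzchar(long$gene)
  if (any(!ok)) message(sum(!ok), " malformed edge row(s) rejected")
  long <- long[ok, , drop = FALSE]
  key <- paste(long$mirna, long$gene, sep = "\r")
  sp <- split(long$source, key)
  first <- long[!duplicated(key), c("mirna", "gene")]
  first <- first[match(names(sp), paste(first$mirna, first$gene, sep = "\r")), ]
  validated <- target_sources()$validated
  out <- data.frame(
    mirna = first$mirna, gene = first$gene,
    sources = vapply(sp, function(s) paste(sort(unique(s)), collapse = ","),
                     character(1)),
    validated = vapply(sp, function(s) any(s %in% validated), logical(1)),
    row.names = NULL)
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_db", "data.frame")
  out
}

#' Retain inversely regulated miRNA-target pairs
#'
#' The cross-omics filter: within each cell line, keeps (miRNA, gene) pairs
#' where the edge exists in the target database, both members pass the fold
#' and significance cut-offs, and the two signed folds have opposite signs.
#' A target whose own fold sits below the cut-off is treated as not
#' significant and the pair is suppressed.
#'
#' @param mir_de long data.frame (`mirna`, `cell_line`, `fold`, `p_adj`).
#' @param gene_de long data.frame (`gene`, `cell_line`, `fold`, `p_adj`).
#' @param db a `target_db` from [aggregate_targets()].
#' @param thr a [thresholds()] object (the call cut-off `fold_cut` and
#'   `alpha` apply to both members).
#' @return data.frame of pair records: `mirna`, `gene`, `cell_line`,
#'   `mir_fold`, `mir_p_adj`, `gene_fold`, `gene_p_adj`, `sources`,
#'   `validated`. miRNAs passing the cut-offs but absent from the database
#'   are counted in a message.
#' @export
select_inverse_pairs <- function(mir_de, gene_de, db, thr = thresholds()) {
  mir_pass <- mir_de[fold_pass(mir_de$fold, thr$fold_cut, thr$strict_fold) &
                     sig_pass(mir_de$p_adj, thr), , drop = FALSE]
  gene_pass <- gene_de[fold_pass(gene_de$fold, thr$fold_cut, thr$strict_fold) &
                       sig_pass(gene_de$p_adj, thr), , drop = FALSE]
  no_target <- setdiff(unique(mir_pass$mirna), unique(db$mirna))
  if (length(no_target))
    message(length(no_target), " differentially expressed miRNA(s) have no ",
            "edge in the target database")
  m <- merge(mir_pass, db, by = "mirna")
  m <- merge(m, gene_pass, by = c("gene", "cell_line"),
             suffixes = c("_mir", "_gene"))
  keep <- sign(m$fold_mir) * sign(m$fold_gene) == -1
  m <- m[keep, , drop = FALSE]
  out <- data.frame(mirna = m$mirna, gene = m$gene,
                    cell_line = m$cell_line,
                    mir_fold = m$fold_mir, mir_p_adj = m$p_adj_mir,
                    gene_fold = m$fold_gene, gene_p_adj = m$p_adj_gene,
                    sources = m$sources, validated = m$validated)
  out <- out[order(out$cell_line, out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(sign(out$mir_fold) * sign(out$gene_fold) == -1))
  out
}

#' Default GO keyword list
#'
#' Terms covering drug resistance, extracellular matrix, and cancer
#' stem-cell biology; the superset of the two keyword lists used in the
#' study workflow.
#'
#' @return character vector of GO term names.
#' @export
default_go_keywords <- function() {
  c("collagen-containing extracellular matrix", "extracellular matrix",
    "extracellular space", "response to drug", "drug transport", "stem cell")
}

#' Subset pairs by GO term keywords
#'
#' Keeps pairs whose target gene carries at least one of the keyword terms
#' (case-insensitive exact term-name match) and records which terms
#' matched. Genes without any annotation are treated as non-matching.
#'
#' @param pairs pair records from [select_inverse_pairs()].
#' @param annotations data.frame with columns `gene` and `term`.
#' @param keywords character vector of term names (non-empty).
#' @return the retained pairs with a `matched_go_terms` column
#'   (comma-separated, case-normalized to lower case).
#' @export
filter_by_go <- function(pairs, annotations, keywords = default_go_keywords()) {
  if (!length(keywords)) stop("keywords must be non-empty")
  if (!all(c("gene", "term") %in% names(annotations)))
    stop("annotations needs columns `gene` and `term`")
  kw <- tolower(keywords)
  ann <- annotations
  ann$term <- tolower(as.character(ann$term))
  ann <- ann[ann$term %in% kw, , drop = FALSE]
  terms_of <- split(ann$term, ann$gene)
  unannotated <- setdiff(unique(pairs$gene), unique(annotations$gene))
  if (length(unannotated))
    message(length(unannotated), " target gene(s) carry no GO annotation")
  matched <- lapply(as.character(pairs$gene), function(g) {
    t <- terms_of[[g]]
    if (is.null(t)) character() else sort(unique(t))
  })
  keep <- lengths(matched) > 0
  out <- pairs[keep, , drop = FALSE]
  out$matched_go_terms <- vapply(matched[keep], paste, character(1),
                                 collapse = ",")
  rownames(out) <- NULL
  out
}

#' Export a miRNA-target network
#'
#' Writes the pair list as a directed miRNA -> gene graph in a
#' Cytoscape-importable format: `sif` (relation token `targets`),
#' `graphml` (with node `type` and edge fold/source/GO attributes), or
#' `tsv` (full pair table; round-trips through [read_pairs()]).
#'
#' @param pairs pair records ([select_inverse_pairs()] /
#'   [filter_by_go()] output).
#' @param path output file path.
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(pairs, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (format != "tsv" && nrow(pairs) == 0L)
    stop("empty pair list: only tsv export supports an empty network")
  if (format == "tsv") {
    write_pairs(pairs, path)
  } else if (format == "sif") {
    writeLines(paste(pairs$mirna, "targets", pairs$gene), path)
  } else {
    writeLines(graphml_document(pairs), path)
  }
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

graphml_document <- function(pairs) {
  mirs <- unique(as.character(pairs$mirna))
  genes <- unique(as.character(pairs$gene))
  node_xml <- c(
    sprintf('    <node id="%s"><data key="type">miRNA</data></node>',
            xml_escape(mirs)),
    sprintf('    <node id="%s"><data key="type">gene</data></node>',
            xml_escape(genes)))
  has_go <- "matched_go_terms" %in% names(pairs)
  edge_xml <- vapply(seq_len(nrow(pairs)), function(i) {
    go <- if (has_go) sprintf('<data key="go">%s</data>',
                              xml_escape(pairs$matched_go_terms[i])) else ""
    sprintf(paste0('    <edge source="%s" target="%s">',
                   '<data key="cell_line">%s</data>',
                   '<data key="mir_fold">%.10g</data>',
                   '<data key="gene_fold">%.10g</data>',
                   '<data key="sources">%s</data>%s</edge>'),
            xml_escape(pairs$mirna[i]), xml_escape(pairs$gene[i]),
            xml_escape(as.character(pairs$cell_line[i])),
            pairs$mir_fold[i], pairs$gene_fold[i],
            xml_escape(as.character(pairs$sources[i])), go)
  }, character(1))
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="type" for="node" attr.name="type" attr.type="string"/>',
    '  <key id="cell_line" for="edge" attr.name="cell_line" attr.type="string"/>',
    '  <key id="mir_fold" for="edge" attr.name="mir_fold" attr.type="double"/>',
    '  <key id="gene_fold" for="edge" attr.name="gene_fold" attr.type="double"/>',
    '  <key id="sources" for="edge" attr.name="sources" attr.type="string"/>',
    '  <key id="go" for="edge" attr.name="go" attr.type="string"/>',
    '  <graph id="mirna_targets" edgedefault="directed">',
    node_xml, edge_xml, "  </graph>", "</graphml>")
}
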