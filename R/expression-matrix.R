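#' Expression matrix with sample group labels
#'
#' The central container of the pipeline: a numeric matrix of log2
#' intensities with features (miRNAs or probes) as rows and samples as
#' columns, plus a group label for every sample. The first group listed in
#' `levels(groups)` is treated as the reference (parental) group by all
#' downstream contrasts.
#'
#' @param values numeric matrix, features x samples; must have rownames
#'   (feature identifiers) and colnames (sample identifiers).
#' @param groups character or factor of length `ncol(values)` assigning each
#'   sample to a group. If a character vector, level order follows first
#'   appearance.
#' @return An object of class `expr_matrix`: the matrix with a `groups`
#'   factor attribute.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("mir", 1:3), paste0("s", 1:4)))
#' em <- expr_matrix(m, groups = c("A", "A", "B", "B"))
#' groups(em)
#' @export
expr_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("feature (row) names must be present and unique")
  if (is.null(colnames(values)))
    stop("sample (column) names must be present")
  if (length(groups) != ncol(values))
    stop("`groups` must have one entry per sample column")
  if (anyNA(values))
    stop("missing values are not supported in expression matrices")
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  structure(values, groups = groups, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
groups <- function(x) {
  g <- attr(x, "groups")
  if (is.null(g)) stop("object carries no group labels")
  g
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples\n", nrow(x), ncol(x)))
  g <- attr(x, "groups")
  cat("groups:", paste(sprintf("%s (n=%d)", levels(g), tabulate(g)),
                       collapse = ", "), "\n")
  cat("reference group:", levels(g)[1], "\n")
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  g <- attr(x, "groups")
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    if (!missing(j)) g <- g[j]
    out <- structure(out, groups = droplevels(g),
                     class = c("expr_matrix", "matrix", "array"))
  }
  out
}

#' Reference group of an expression matrix
#'
#' @param x an `expr_matrix`.
#' @return the name of the reference group (first factor level).
#' @export
reference_group <- function(x) levels(groups(x))[1]
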