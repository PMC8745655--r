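#' Quantile normalization across samples
#'
#' Forces every sample column to share the same empirical distribution: each
#' column's order statistics are replaced by the across-sample mean of the
#' order statistics, mapped back by within-column rank. This is the
#' normalization step of the RMA core for single-channel arrays.
#'
#' Tied values within a column receive the mean of the order-statistic means
#' of the tied ranks, so the operation is invariant to the order in which
#' tied entries are listed.
#'
#' @param x numeric matrix (features/probes x samples) or `expr_matrix`.
#'   No missing values allowed.
#' @return A matrix of the same shape and class; after normalization the
#'   multiset of values in every column is identical.
#' @examples
#' m <- cbind(a = c(1, 2), b = c(3, 4))
#' rownames(m) <- c("f1", "f2")
#' quantile_normalize(m)  # both columns become (2, 3)
#' @export
quantile_normalize <- function(x) {
  if (anyNA(x)) stop("missing values are not supported")
  if (ncol(x) < 2L) {
    warning("fewer than 2 sample columns; matrix returned unchanged")
    return(x)
  }
  sorted <- apply(unclass(x), 2L, sort)
  ref <- rowMeans(sorted)
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    tmp <- numeric(length(v))
    tmp[order(v)] <- ref
    # tied cells share the mean of the order-statistic means of their ranks
    out[, j] <- stats::ave(tmp, v, FUN = mean)
  }
  out
}

#' Median-polish summarization of probe-level values
#'
#' The summarization step of the RMA core: for each feature, fits an
#' additive model (probe effect + sample effect + residual) to its probes'
#' quantile-normalized log2 values by alternating median sweeps, and reports
#' overall + sample effect as the feature's per-sample expression.
#'
#' @param probe_values numeric matrix, probes x samples, with probe row
#'   names and sample column names.
#' @param probe_map data.frame with columns `probe` and `feature` mapping
#'   every probe row to exactly one feature.
#' @param tol convergence tolerance on the residual sweep (default 1e-6).
#' @param max_iter maximum number of sweep cycles (default 10).
#' @param groups optional group labels for the resulting `expr_matrix`;
#'   if `NULL` a plain matrix is returned.
#' @return features x samples matrix (or `expr_matrix` when `groups` is
#'   given) of summarized expression values.
#' @seealso [quantile_normalize()]
#' @export
median_polish_summarize <- function(probe_values, probe_map, tol = 1e-6,
                                    max_iter = 10L, groups = NULL) {
  if (anyNA(probe_values) || any(!is.finite(probe_values)))
    stop("probe matrix contains non-finite values")
  if (!all(c("probe", "feature") %in% names(probe_map)))
    stop("probe_map needs columns `probe` and `feature`")
  if (anyDuplicated(probe_map$probe))
    stop("every probe must map to exactly one feature")
  missing_probes <- setdiff(rownames(probe_values), probe_map$probe)
  if (length(missing_probes))
    stop("unmapped probes: ", paste(utils::head(missing_probes, 5), collapse = ", "))
  feat_of <- probe_map$feature[match(rownames(probe_values), probe_map$probe)]
  features <- unique(probe_map$feature[probe_map$probe %in% rownames(probe_values)])
  out <- matrix(NA_real_, length(features), ncol(probe_values),
                dimnames = list(features, colnames(probe_values)))
  for (f in features) {
    sub <- probe_values[feat_of == f, , drop = FALSE]
    if (nrow(sub) == 0L) stop("feature with no probes: ", f)
    fit <- median_polish(sub, tol = tol, max_iter = max_iter)
    out[f, ] <- fit$overall + fit$col
  }
  if (!is.null(groups)) out <- expr_matrix(out, groups)
  out
}

#' Tukey median polish of a two-way table
#'
#' Iteratively sweeps row and column medians out of a matrix until the
#' largest absolute change between cycles falls below `tol` or `max_iter`
#' cycles are exhausted. Workhorse of [median_polish_summarize()], exported
#' because the decomposition itself is occasionally useful.
#'
#' @param x numeric matrix.
#' @param tol convergence tolerance (default 1e-6).
#' @param max_iter maximum sweep cycles (default 10).
#' @return list with `overall` (scalar), `row` and `col` effect vectors,
#'   `residuals` matrix, and `iterations` used.
#' @export
median_polish <- function(x, tol = 1e-6, max_iter = 10L) {
  x <- unclass(x)
  overall <- 0
  row_eff <- rep(0, nrow(x))
  col_eff <- rep(0, ncol(x))
  res <- x
  for (it in seq_len(max_iter)) {
    old <- res
    rmed <- apply(res, 1L, stats::median)
    res <- res - rmed
    row_eff <- row_eff + rmed
    cmed_of_row <- stats::median(row_eff)
    row_eff <- row_eff - cmed_of_row
    overall <- overall + cmed_of_row
    cmed <- apply(res, 2L, stats::median)
    res <- sweep(res, 2L, cmed)
    col_eff <- col_eff + cmed
    rmed_of_col <- stats::median(col_eff)
    col_eff <- col_eff - rmed_of_col
    overall <- overall + rmed_of_col
    if (max(abs(res - old)) < tol) break
  }
  list(overall = overall, row = row_eff, col = col_eff,
       residuals = res, iterations = it)
}

#' Optional background floor correction
#'
#' A documented simplification of RMA's normal-exponential background
#' model: subtracts a low-quantile noise floor per sample on the intensity
#' scale and clamps at a small positive value before returning to log2.
#' Off by default in the pipeline; matrices are assumed already log2.
#'
#' @param x log2 matrix or `expr_matrix`.
#' @param floor_quantile quantile used as the per-sample noise floor
#'   (default 0.05).
#' @param eps positive clamp applied on the intensity scale (default 1).
#' @return matrix of the same shape, background-adjusted, in log2 units.
#' @export
background_floor <- function(x, floor_quantile = 0.05, eps = 1) {
  if (floor_quantile < 0 || floor_quantile >= 1)
    stop("floor_quantile must lie in [0, 1)")
  raw <- 2^unclass(x)
  floors <- apply(raw, 2L, stats::quantile, probs = floor_quantile)
  adj <- pmax(sweep(raw, 2L, floors), eps)
  out <- log2(adj)
  if (inherits(x, "expr_matrix")) out <- expr_matrix(out, groups(x))
  out
}
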