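#' Signed fold change from a log2 difference
#'
#' Converts a log2 difference to the signed multiplicative fold convention
#' used throughout miRNA array reports: ratios >= 1 are printed as-is,
#' ratios < 1 as minus their reciprocal, so a halving prints as -2 rather
#' than 0.5. A log2 difference of exactly 0 maps to +1 (the sign ambiguity
#' at zero is resolved to positive).
#'
#' @param log2_diff numeric vector of log2 differences.
#' @return signed fold changes with `|fold| >= 1`.
#' @examples
#' signed_fold(c(1, -1, 0))   # +2, -2, +1
#' @export
signed_fold <- function(log2_diff) {
  if (any(!is.finite(log2_diff))) stop("log2_diff must be finite")
  ifelse(log2_diff >= 0, 2^log2_diff, -(2^(-log2_diff)))
}

#' Log2 difference from a signed fold change
#'
#' Inverse of [signed_fold()]; defined for `|fold| >= 1`.
#'
#' @param fold signed fold changes.
#' @return log2 differences.
#' @export
fold_to_log2 <- function(fold) {
  if (any(abs(fold) < 1)) stop("signed folds must satisfy |fold| >= 1")
  ifelse(fold >= 0, log2(fold), -log2(-fold))
}

#' Per-feature two-group effect and pooled variance
#'
#' First stage of the per-contrast linear model: for each feature computes
#' the mean log2 difference between two groups and the pooled within-group
#' variance on `n_a + n_b - 2` degrees of freedom. Features whose replicates
#' are identical in both groups get `s2 = 0` and are flagged.
#'
#' @param x an `expr_matrix`.
#' @param group_a,group_b group names; the effect is `mean(a) - mean(b)`
#'   (so `group_b` is typically the parental reference).
#' @return data.frame: `feature`, `log2_diff`, `s2`, `d_resid`, `n_a`,
#'   `n_b`, `zero_variance` flag.
#' @export
fit_contrast <- function(x, group_a, group_b = reference_group(x)) {
  g <- groups(x)
  if (!group_a %in% levels(g) || !group_b %in% levels(g))
    stop("unknown group: ", setdiff(c(group_a, group_b), levels(g))[1])
  a <- unclass(x)[, g == group_a, drop = FALSE]
  b <- unclass(x)[, g == group_b, drop = FALSE]
  n_a <- ncol(a); n_b <- ncol(b)
  if (n_a < 2L || n_b < 2L) stop("both groups need >= 2 samples")
  log2_diff <- rowMeans(a) - rowMeans(b)
  ss_a <- rowSums((a - rowMeans(a))^2)
  ss_b <- rowSums((b - rowMeans(b))^2)
  d_resid <- n_a + n_b - 2L
  s2 <- (ss_a + ss_b) / d_resid
  data.frame(feature = rownames(x), log2_diff = log2_diff, s2 = s2,
             d_resid = d_resid, n_a = n_a, n_b = n_b,
             zero_variance = s2 == 0, row.names = NULL)
}

#' Inverse of the trigamma function
#'
#' Newton iteration for `trigamma(x) = y`, used by the empirical-Bayes
#' moment estimator of the prior degrees of freedom.
#'
#' @param y positive values.
#' @return x such that `trigamma(x) = y`.
#' @keywords internal
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(NaN)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (-dif / x < 1e-8) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks per-feature residual variances toward a pooled prior by fitting a
#' scaled F (equivalently, scaled inverse chi-square) distribution to the
#' sample variances via moment matching of log variances: the excess of the
#' empirical variance of `log(s2)` over `trigamma(d/2)` identifies the prior
#' degrees of freedom `d0` through the trigamma relation, and the mean of
#' the adjusted log variances identifies the prior variance `s0_2`. When the
#' log variances are no more dispersed than sampling alone explains, the
#' variances are treated as homogeneous: `d0 = Inf` and every posterior
#' variance equals `s0_2`.
#'
#' @param s2 per-feature residual variances (zero-variance features are
#'   excluded from estimation but still receive a posterior value).
#' @param d_resid residual degrees of freedom (scalar; balanced designs).
#' @return list: `d0`, `s0_2`, and `s2_post` (posterior variances,
#'   `(d0*s0_2 + d_resid*s2) / (d0 + d_resid)`).
#' @export
ebayes_moderate <- function(s2, d_resid) {
  if (length(d_resid) != 1L || d_resid < 1)
    stop("d_resid must be a single value >= 1")
  use <- is.finite(s2) & s2 > 0
  if (sum(use) < 10L)
    stop("need >= 10 features with positive variance to estimate the prior")
  z <- log(s2[use])
  e <- z - digamma(d_resid / 2) + log(d_resid / 2)
  e_mean <- mean(e)
  n <- length(e)
  e_var <- sum((e - e_mean)^2) / (n - 1L) - trigamma(d_resid / 2)
  if (e_var > 0) {
    d0 <- 2 * trigamma_inverse(e_var)
    s0_2 <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_2 + d_resid * s2) / (d0 + d_resid)
  } else {
    d0 <- Inf
    s0_2 <- mean(s2[use])
    s2_post <- rep(s0_2, length(s2))
  }
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post)
}

#' Moderated t-statistic and two-sided p-value
#'
#' @param log2_diff per-feature effects.
#' @param s2_post posterior variances from [ebayes_moderate()] (or raw
#'   variances for the classical test, `d0 = 0`).
#' @param n_a,n_b group sizes.
#' @param d_resid residual degrees of freedom.
#' @param d0 prior degrees of freedom; total df is `d0 + d_resid`, with
#'   `d0 = Inf` giving a normal reference.
#' @return data.frame with `t_mod` and `p_raw`; features with zero
#'   posterior variance get `NA` in both.
#' @export
moderated_t <- function(log2_diff, s2_post, n_a, n_b, d_resid, d0 = 0) {
  se <- sqrt(s2_post * (1 / n_a + 1 / n_b))
  t_mod <- ifelse(se > 0, log2_diff / se, NA_real_)
  df <- d0 + d_resid
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df)
  data.frame(t_mod = t_mod, p_raw = p_raw)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `p_adj(i) = min over k with p(k) >= p(i) of m * p(k) / rank(k)`,
#' capped at 1; order-preserving.
#'
#' @param p raw p-values in `[0, 1]`; `NA`s are propagated and excluded
#'   from the multiplicity count.
#' @return adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    out[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  }
  out
}

#' Full differential-expression contrast
#'
#' Runs [fit_contrast()], [ebayes_moderate()], [moderated_t()] and
#' [adjust_bh()] for one resistant-vs-parental comparison and attaches the
#' signed fold change.
#'
#' @inheritParams fit_contrast
#' @param moderate logical; shrink variances via empirical Bayes
#'   (default `TRUE`). With `FALSE` the classical pooled-variance t-test is
#'   used.
#' @return data.frame: `feature`, `log2_diff`, `signed_fold`, `s2`,
#'   `s2_post`, `t_mod`, `p_raw`, `p_adj`, `d_resid`, `d0`, `s0_2`.
#'   Zero-variance features (flagged by [fit_contrast()]) carry `NA`
#'   statistics when variances cannot be shrunk.
#' @examples
#' sim <- simulate_expression(sim_config(n_features = 50, seed = 1))
#' de <- run_contrast(sim$matrix, "A2780CR1")
#' head(de)
#' @export
run_contrast <- function(x, group_a, group_b = reference_group(x),
                         moderate = TRUE) {
  fit <- fit_contrast(x, group_a, group_b)
  if (moderate) {
    eb <- ebayes_moderate(fit$s2, fit$d_resid[1])
    d0 <- eb$d0; s0_2 <- eb$s0_2; s2_post <- eb$s2_post
  } else {
    d0 <- 0; s0_2 <- NA_real_; s2_post <- fit$s2
  }
  mt <- moderated_t(fit$log2_diff, s2_post, fit$n_a[1], fit$n_b[1],
                    fit$d_resid[1], d0)
  data.frame(feature = fit$feature,
             log2_diff = fit$log2_diff,
             signed_fold = signed_fold(fit$log2_diff),
             s2 = fit$s2, s2_post = s2_post,
             t_mod = mt$t_mod, p_raw = mt$p_raw,
             p_adj = adjust_bh(mt$p_raw),
             d_resid = fit$d_resid, d0 = d0, s0_2 = s0_2,
             row.names = NULL)
}

#' All resistant-vs-reference contrasts of a panel
#'
#' @param x an `expr_matrix`; every non-reference group is contrasted
#'   against the reference.
#' @param moderate passed to [run_contrast()].
#' @return long data.frame with a `cell_line` column stacked over contrasts.
#' @export
run_all_contrasts <- function(x, moderate = TRUE) {
  ref <- reference_group(x)
  lines <- setdiff(levels(groups(x)), ref)
  res <- lapply(lines, function(ln) {
    out <- run_contrast(x, ln, ref, moderate = moderate)
    cbind(cell_line = ln, out)
  })
  do.call(rbind, res)
}
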