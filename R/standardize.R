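#' Standardize each sample column to mean 0, variance 1
#'
#' Sample-wise standardization puts every sample on the same scale so that
#' principal components of the sample cloud reflect correlation structure
#' rather than per-sample intensity differences. The variance denominator is
#' the sample variance (n - 1); every column has the same length, so this
#' choice rescales all columns identically and cannot change component
#' directions.
#'
#' @param expr Expression tibble (features x samples).
#' @return Expression tibble with each sample column centered and scaled;
#'   row and column order preserved.
#' @export
standardize_samples <- function(expr) {
  m <- expr_matrix(expr)
  if (any(!is.finite(m))) abort("expression values must be finite")
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  if (any(s == 0)) {
    abort(sprintf("zero-variance sample column: %s", colnames(m)[s == 0][1]))
  }
  as_expression(sweep(sweep(m, 2, mu, "-"), 2, s, "/"))
}

#' Locally weighted polynomial smoothing of an age profile
#'
#' Fits a local polynomial (tricube weights over the span-nearest neighbours)
#' to one expression profile over age and evaluates it at the observed ages.
#' Used to damp subject- or age-estimation-related variation before
#' modelling global developmental patterns. Defaults: local linear fit,
#' span 0.7.
#'
#' @param profile Numeric vector of expression values.
#' @param ages Numeric vector of ages (days), same length; strictly
#'   increasing once sorted (no duplicate ages).
#' @param span Fraction of points in each local neighbourhood, in (0, 1].
#' @param degree Local polynomial degree (0, 1 or 2).
#' @return Smoothed values at the observed ages, in the input order.
#' @export
smooth_profile <- function(profile, ages, span = 0.7, degree = 1) {
  n <- length(profile)
  if (length(ages) != n) abort("profile and ages differ in length")
  if (n < max(4, degree + 2)) abort(sprintf("need at least %d points", max(4, degree + 2)))
  if (anyDuplicated(ages)) abort("ages must be strictly increasing after sorting (duplicates found)")
  if (span <= 0 || span > 1) abort("span must be in (0, 1]")
  if (floor(span * n) < degree + 1) {
    abort(sprintf("span %.3g covers fewer than degree + 1 = %d points", span, degree + 1))
  }
  fit <- loess(
    y ~ x,
    data = data.frame(x = ages, y = profile),
    span = span, degree = degree, family = "gaussian",
    surface = "direct"
  )
  as.numeric(predict(fit, newdata = data.frame(x = ages)))
}

#' Smooth every feature profile of a time series
#'
#' Applies [smooth_profile()] to every feature, within each replicate series
#' separately when `meta` carries more than one replicate.
#'
#' @param expr Expression tibble.
#' @param meta Metadata with `sample_id`, `age_days`, `replicate_id`.
#' @inheritParams smooth_profile
#' @return Expression tibble of smoothed values, same shape and order.
#' @export
smooth_expression <- function(expr, meta, span = 0.7, degree = 1) {
  m <- expr_matrix(expr)
  meta <- meta[match(colnames(m), meta$sample_id), ]
  if (any(is.na(meta$sample_id))) abort("metadata missing some samples of the expression table")
  rep_id <- meta$replicate_id
  rep_id[is.na(rep_id)] <- "rep1"
  out <- m
  for (r in unique(rep_id)) {
    cols <- which(rep_id == r)
    ord <- cols[order(meta$age_days[cols])]
    ages <- meta$age_days[ord]
    out[, ord] <- t(apply(m[, ord, drop = FALSE], 1, smooth_profile,
                          ages = ages, span = span, degree = degree))
  }
  as_expression(out)
}
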