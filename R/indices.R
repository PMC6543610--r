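#' Slope index of inequality (SII)
#'
#' The SII is the slope of the weighted least-squares regression of
#' group-specific event rates on ridit scores, with weights proportional to
#' the population share of each group. It measures absolute inequality in
#' rate units per unit of relative rank and is negative when rates decline
#' with rising socio-economic level.
#'
#' The closed form is the weighted covariance of (ridit, rate) divided by the
#' weighted variance of the ridits:
#' \deqn{SII = \frac{\sum_i w_i (y_i - \bar y_w)(x_i - \bar x_w)}
#'                  {\sum_i w_i (x_i - \bar x_w)^2}}
#' where \eqn{x_i} is the ridit, \eqn{y_i} the rate and \eqn{w_i} the share
#' of level \eqn{i}, and the bars denote share-weighted means.
#'
#' @param shares Population shares per level, lowest level first.
#' @param rates Event rates per 100,000 person-years, aligned with `shares`.
#' @return The signed slope, in rate units.
#' @examples
#' sii(c(0.40, 0.25, 0.25, 0.10), c(750, 550, 450, 300))  # about -559.3
#' @export
sii <- function(shares, rates) {
  p <- as.numeric(as_eld(shares))
  y <- rate_schedule(rates, p)
  x <- ridit_scores(p)
  xbar <- sum(p * x)
  sxx <- sum(p * (x - xbar)^2)
  if (sxx <= .Machine$double.eps)
    stop("degenerate rank variance: all population mass at one ridit", call. = FALSE)
  ybar <- sum(p * y)
  sum(p * (y - ybar) * (x - xbar)) / sxx
}

# Weighted regression line through (ridit, rate): list(slope, intercept).
# Shared by rii(), inequality_indices() and the CI machinery.
rank_regression <- function(p, y) {
  x <- ridit_scores(p)
  xbar <- sum(p * x)
  ybar <- sum(p * y)
  sxx <- sum(p * (x - xbar)^2)
  if (sxx <= .Machine$double.eps)
    stop("degenerate rank variance: all population mass at one ridit", call. = FALSE)
  slope <- sum(p * (y - ybar) * (x - xbar)) / sxx
  list(slope = slope, intercept = ybar - slope * xbar)
}

#' Relative index of inequality (RII, Kunst-Mackenbach ratio)
#'
#' The RII extrapolates the rank regression line of [sii()] to the extremes of
#' the rank axis and reports the ratio of the fitted rate at the bottom of the
#' social hierarchy (the intercept) to the fitted rate at the top (intercept
#' plus slope):
#' \deqn{RII = \frac{Intercept}{Intercept + Slope}}
#' Values above 1 indicate higher rates at the bottom of the hierarchy.
#'
#' The fitted rate at the top of the scale can become non-positive for steep
#' negative gradients; that is an extrapolation failure of the linear model
#' and is reported as an error rather than clamped.
#'
#' @inheritParams sii
#' @return Dimensionless ratio.
#' @examples
#' rii(c(0.40, 0.25, 0.25, 0.10), c(750, 550, 450, 300))  # about 2.86
#' @export
rii <- function(shares, rates) {
  p <- as.numeric(as_eld(shares))
  y <- rate_schedule(rates, p)
  fit <- rank_regression(p, y)
  top <- fit$intercept + fit$slope
  if (top <= 0)
    stop("fitted rate at the top of the rank scale is <= 0; RII undefined",
         call. = FALSE)
  fit$intercept / top
}

#' Population attributable fraction (PAF)
#'
#' Fraction of all events that would be avoided if the whole population
#' experienced the rate of the highest (best-off) socio-economic level:
#' \deqn{PAF = \frac{\bar y_w - y_{ref}}{\bar y_w}}
#' with \eqn{\bar y_w} the share-weighted mean rate and \eqn{y_{ref}} the rate
#' of the reference (by default the highest, i.e. last) level.
#'
#' @inheritParams sii
#' @param reference Index of the reference level; defaults to the last
#'   (highest) level.
#' @return Dimensionless fraction; 0 when all rates are equal.
#' @examples
#' paf(c(0.40, 0.25, 0.25, 0.10), c(750, 550, 450, 300))  # about 0.483
#' @export
paf <- function(shares, rates, reference = length(rates)) {
  p <- as.numeric(as_eld(shares))
  y <- rate_schedule(rates, p)
  if (reference < 1L || reference > length(y))
    stop("reference level index out of range", call. = FALSE)
  ybar <- sum(p * y)
  if (ybar <= 0) stop("mean rate is zero; PAF undefined", call. = FALSE)
  (ybar - y[reference]) / ybar
}

#' Pairwise rate differences and rate ratios
#'
#' Compares each level's rate with a reference level on the absolute scale
#' (rate difference) and the relative scale (rate ratio). Unlike the summary
#' indices, pairwise differentials do not depend on the population shares.
#'
#' @param rates Event rates per 100,000 person-years, lowest level first.
#' @param reference Index of the reference level; defaults to the last
#'   (highest) level.
#' @return A data frame with one row per level: `level`, `rate`,
#'   `difference` (rate minus reference rate) and `ratio` (rate over
#'   reference rate, `NA` if the reference rate is zero).
#' @examples
#' pairwise_rates(c(630, 500, 400, 290))
#' @export
pairwise_rates <- function(rates, reference = length(rates)) {
  y <- rate_schedule(rates)
  if (reference < 1L || reference > length(y))
    stop("reference level index out of range", call. = FALSE)
  ref <- y[reference]
  data.frame(
    level = paste0("EL", seq_along(y)),
    rate = y,
    reference = paste0("EL", reference),
    difference = y - ref,
    ratio = if (ref > 0) y / ref else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' All inequality indices for one stratified population
#'
#' Single-pass computation of the SII, RII and PAF plus the fitted regression
#' quantities and the pairwise differentials, from one (distribution,
#' schedule) pair. All values are kept in full precision; rounding is a
#' reporting concern (see [format.inequality_indices()] and
#' [indices_json()]).
#'
#' @inheritParams sii
#' @param reference Reference level for the PAF and pairwise comparisons;
#'   defaults to the last (highest) level.
#' @return An object of class `"inequality_indices"`: a list with elements
#'   `sii`, `rii`, `paf`, `intercept`, `fitted_top`, `mean_rate`, `shares`,
#'   `rates`, `ridits`, `reference` and `pairwise` (a data frame).
#' @examples
#' inequality_indices(c(0.40, 0.25, 0.25, 0.10), c(750, 550, 450, 300))
#' @export
inequality_indices <- function(shares, rates, reference = length(rates)) {
  p <- as.numeric(as_eld(shares))
  y <- rate_schedule(rates, p)
  fit <- rank_regression(p, y)
  top <- fit$intercept + fit$slope
  ybar <- sum(p * y)
  structure(list(
    sii = fit$slope,
    rii = if (top > 0) fit$intercept / top else NA_real_,
    paf = paf(p, y, reference),
    intercept = fit$intercept,
    fitted_top = top,
    mean_rate = ybar,
    shares = p,
    rates = y,
    ridits = ridit_scores(p),
    reference = reference,
    pairwise = pairwise_rates(y, reference)
  ), class = "inequality_indices")
}

#' @rdname inequality_indices
#' @param x An `inequality_indices` object.
#' @param digits_ratio Decimal places for RII and PAF in the display; the SII
#'   is displayed to the nearest integer.
#' @param ... Unused.
#' @export
format.inequality_indices <- function(x, digits_ratio = 2, ...) {
  c(sii = sprintf("%.0f", x$sii),
    rii = if (is.na(x$rii)) "undefined" else
      sprintf(paste0("%.", digits_ratio, "f"), x$rii),
    paf = sprintf(paste0("%.", digits_ratio, "f"), x$paf))
}

#' @export
print.inequality_indices <- function(x, ...) {
  f <- format(x, ...)
  cat("Inequality indices (", length(x$shares), " levels, reference EL",
      x$reference, ")\n", sep = "")
  cat("  SII:", f[["sii"]], "per 100,000 person-years per unit rank\n")
  cat("  RII:", f[["rii"]], "\n")
  cat("  PAF:", f[["paf"]], "\n")
  cat("  mean rate:", sprintf("%.2f", x$mean_rate),
      " fitted bottom/top:", sprintf("%.2f / %.2f", x$intercept, x$fitted_top),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.inequality_indices <- function(x, ...) {
  data.frame(sii = x$sii, rii = x$rii, paf = x$paf,
             intercept = x$intercept, fitted_top = x$fitted_top,
             mean_rate = x$mean_rate)
}
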