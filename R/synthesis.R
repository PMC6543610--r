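#' Expected stratified population at a rate schedule
#'
#' Builds the deterministic (noise-free) population implied by a
#' distribution, a rate schedule and a total amount of person-years: each
#' level receives `share * total` person-years and its real-valued expected
#' death count `rate * person_years / 1e5`. Indices computed on this
#' population reproduce the closed-form indices exactly, which makes it the
#' anchoring case for the stochastic sampler.
#'
#' @param shares Population shares per level, lowest level first.
#' @param rates Event rates per 100,000 person-years.
#' @param total_person_years Total person-years over all levels (> 0).
#' @return Data frame of class `"synthetic_population"` with one row per
#'   level: `level_label`, `share`, `person_years`, `deaths`, `rate`
#'   (observed rate per 100,000 person-years).
#' @examples
#' expected_counts(c(0.4, 0.25, 0.25, 0.1), belgium_rates_2001(), 1e6)
#' @export
expected_counts <- function(shares, rates, total_person_years) {
  p <- as.numeric(as_eld(shares))
  y <- rate_schedule(rates, p)
  if (!is.finite(total_person_years) || total_person_years <= 0)
    stop("total_person_years must be a positive number", call. = FALSE)
  py <- p * total_person_years
  deaths <- y * py / 1e5
  structure(data.frame(
    level_label = paste0("EL", seq_along(p)),
    share = p,
    person_years = py,
    deaths = deaths,
    rate = deaths / py * 1e5,
    stringsAsFactors = FALSE
  ), class = c("synthetic_population", "data.frame"))
}

#' Sample a stratified population with Poisson death counts
#'
#' Draws each level's death count from a Poisson distribution whose mean is
#' the expected count of [expected_counts()]. Poisson sampling is the
#' standard model for rare-event counts over person-years at risk. The draw
#' is fully determined by `seed`; no global random state is consulted or
#' altered beyond the call.
#'
#' @inheritParams expected_counts
#' @param seed Integer seed; required, so every sample is reproducible.
#' @return A `"synthetic_population"` data frame with integer `deaths` and
#'   the corresponding observed `rate` per 100,000 person-years.
#' @examples
#' sample_population(c(0.4, 0.25, 0.25, 0.1), belgium_rates_2001(), 1e6, seed = 7)
#' @export
sample_population <- function(shares, rates, total_person_years, seed) {
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  pop <- expected_counts(shares, rates, total_person_years)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  pop$deaths <- stats::rpois(nrow(pop), lambda = pop$deaths)
  pop$rate <- pop$deaths / pop$person_years * 1e5
  pop
}

# Analytic WLS inference on the rank regression, from a population with
# person-years. Weights are the population shares; the sampling variance of
# each observed rate is Poisson, var(y_i) = y_i * 1e5 / py_i on the
# per-100,000 scale (expected rate estimated by the observed one). Slope and
# intercept are linear in the rates, so their variances and covariance
# follow by direct propagation; the RII interval is a delta-method interval
# on the log scale.
rank_regression_inference <- function(p, y, py, ci_level) {
  x <- ridit_scores(p)
  xbar <- sum(p * x)
  sxx <- sum(p * (x - xbar)^2)
  if (sxx <= .Machine$double.eps)
    stop("degenerate rank variance: all population mass at one ridit", call. = FALSE)
  cs <- p * (x - xbar) / sxx          # slope = sum(cs * y)
  ca <- p - xbar * cs                 # intercept = sum(ca * y)
  v <- y * 1e5 / py                   # Poisson variance of each observed rate
  slope <- sum(cs * y)
  intercept <- sum(ca * y)
  var_b1 <- sum(cs^2 * v)
  var_b0 <- sum(ca^2 * v)
  cov_b01 <- sum(ca * cs * v)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  top <- intercept + slope
  sii_ci <- slope + c(-1, 1) * z * sqrt(var_b1)
  if (top > 0 && intercept > 0) {
    # d log RII / d(b0, b1) with RII = b0 / (b0 + b1)
    g0 <- 1 / intercept - 1 / top
    g1 <- -1 / top
    var_log_rii <- g0^2 * var_b0 + g1^2 * var_b1 + 2 * g0 * g1 * cov_b01
    rii <- intercept / top
    rii_ci <- exp(log(rii) + c(-1, 1) * z * sqrt(max(var_log_rii, 0)))
  } else {
    rii <- NA_real_
    rii_ci <- c(NA_real_, NA_real_)
  }
  list(slope = slope, intercept = intercept, rii = rii,
       se_sii = sqrt(var_b1), sii_ci = sii_ci, rii_ci = rii_ci)
}

#' Inequality indices with confidence intervals from a synthetic population
#'
#' Point estimates come from the observed rates through the same closed
#' forms as [inequality_indices()]. The SII interval uses the analytic
#' standard error of the weighted least-squares slope with Poisson-rate
#' variances (each observed rate's variance is `rate * 1e5 / person_years`);
#' the RII interval is a delta-method interval on the log of the
#' intercept-to-top ratio, using the propagated variances and covariance of
#' the fitted intercept and slope. The method is exposed through the
#' `ci_method` argument so alternative interval strategies can be plugged in
#' without touching callers.
#'
#' @param population A `"synthetic_population"` data frame
#'   ([expected_counts()] or [sample_population()]), all person-years > 0.
#' @param ci_level Confidence level (default 0.95).
#' @param reference Reference level for the PAF; defaults to the last level.
#' @param ci_method Interval strategy; only `"wls_delta"` is built in.
#' @return List with `indices` (an [inequality_indices()] object computed
#'   from the observed rates) and `ci`, a 2-column matrix with rows `sii`
#'   and `rii` giving lower and upper bounds.
#' @examples
#' pop <- sample_population(c(0.4, 0.25, 0.25, 0.1), belgium_rates_2001(),
#'                          1e7, seed = 1)
#' indices_with_ci(pop)$ci
#' @export
indices_with_ci <- function(population, ci_level = 0.95,
                            reference = nrow(population),
                            ci_method = "wls_delta") {
  stopifnot(inherits(population, "data.frame"),
            all(c("share", "person_years", "deaths", "rate") %in% names(population)))
  if (any(population$person_years <= 0))
    stop("all person-years must be positive", call. = FALSE)
  ci_method <- match.arg(ci_method, "wls_delta")
  p <- population$share / sum(population$share)
  y <- population$rate
  inf <- rank_regression_inference(p, y, population$person_years, ci_level)
  ix <- inequality_indices(p, y, reference)
  ci <- rbind(sii = inf$sii_ci, rii = inf$rii_ci)
  colnames(ci) <- c("lower", "upper")
  list(indices = ix, ci = ci, se_sii = inf$se_sii, level = ci_level,
       method = ci_method)
}
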