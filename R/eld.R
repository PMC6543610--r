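#' Educational-level distribution
#'
#' Constructs and validates a distribution of population shares over ordered
#' socio-economic groups (typically educational levels), lowest level first.
#' Shares must be strictly positive and sum to one; at least two levels are
#' required, because the rank regression behind the slope and relative indices
#' of inequality is undefined for a single group.
#'
#' @param shares Numeric vector of group shares, lowest socio-economic level
#'   first. Must be strictly positive and sum to 1 (tolerance `1e-9`).
#' @return A numeric vector of class `"eld"`.
#' @examples
#' eld(c(0.40, 0.25, 0.25, 0.10))
#' @export
eld <- function(shares) {
  shares <- as.numeric(shares)
  if (length(shares) < 2L)
    stop("an educational-level distribution needs at least 2 levels", call. = FALSE)
  if (anyNA(shares) || any(shares <= 0))
    stop("all shares must be strictly positive", call. = FALSE)
  if (abs(sum(shares) - 1) > 1e-9)
    stop(sprintf("shares must sum to 1 (got %.12g)", sum(shares)), call. = FALSE)
  structure(shares, class = "eld")
}

#' @export
print.eld <- function(x, ...) {
  cat("Educational-level distribution (", length(x), " levels, lowest first):\n",
      sep = "")
  print(setNames(round(unclass(x), 6), paste0("p", seq_along(x))))
  invisible(x)
}

# Accept either an eld object or a raw numeric vector; always validate.
as_eld <- function(shares) {
  if (inherits(shares, "eld")) shares else eld(shares)
}

#' Validate a mortality (event-rate) schedule against a distribution
#'
#' A schedule is a vector of event rates per 100,000 person-years, one per
#' socio-economic level, aligned with the distribution (lowest level first).
#' Rates are kept in their input units throughout; nothing is rescaled.
#'
#' @param rates Numeric vector of non-negative rates per 100,000 person-years.
#' @param shares Optional distribution to check alignment against.
#' @return The validated numeric rate vector, invisibly usable as-is.
#' @export
rate_schedule <- function(rates, shares = NULL) {
  rates <- as.numeric(rates)
  if (length(rates) < 1L || anyNA(rates) || any(rates < 0))
    stop("rates must be non-negative and free of NA", call. = FALSE)
  if (!is.null(shares) && length(rates) != length(shares))
    stop(sprintf("schedule has %d rates but the distribution has %d levels",
                 length(rates), length(shares)), call. = FALSE)
  rates
}

#' Ridit scores of an ordered distribution
#'
#' The ridit of a group is the midpoint of its cumulative population-share
#' range once the groups are ordered from the lowest to the highest
#' socio-economic level. Ridits encode the relative social rank of each group
#' on a 0-1 axis (0 = bottom of the hierarchy, 1 = top) and serve as the
#' regressor of the rank regression underlying the SII and RII.
#'
#' The share-weighted mean of the ridits is exactly 0.5 for every valid
#' distribution, an algebraic identity that pins the regression's weighted
#' centroid to the middle of the rank axis.
#'
#' @inheritParams eld
#' @return Numeric vector of ridits, strictly increasing, in (0, 1).
#' @examples
#' ridit_scores(c(0.40, 0.25, 0.25, 0.10))  # 0.200 0.525 0.775 0.950
#' @export
ridit_scores <- function(shares) {
  p <- as.numeric(as_eld(shares))
  cum <- cumsum(p)
  (c(0, cum[-length(cum)]) + cum) / 2
}
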