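#' Specification of a hypothetical-distribution grid
#'
#' Defines the lattice of educational-level distributions explored by the
#' composition-shift simulation: the shares of the first `n_levels - 1`
#' levels run over a regular grid between `lower` and `upper`, the last
#' share is the complement to 1, and only combinations with every share
#' inside `[lower, upper]` are retained.
#'
#' Shares are handled as exact integer-valued percents on the lattice, which
#' makes enumeration and family extraction immune to floating-point
#' set-membership surprises; they are converted to fractions at evaluation.
#'
#' @param n_levels Number of socio-economic levels (4 by default).
#' @param lower,upper Admissible share bounds as fractions (defaults 0.05
#'   and 0.50).
#' @param step Grid increment as a fraction (default 0.05); must divide the
#'   bound range.
#' @return A list of class `"grid_spec"`.
#' @examples
#' grid_spec()
#' @export
grid_spec <- function(n_levels = 4L, lower = 0.05, upper = 0.50, step = 0.05) {
  if (n_levels < 2L) stop("need at least 2 levels", call. = FALSE)
  if (!(lower > 0 && lower <= upper && upper < 1))
    stop("bounds must satisfy 0 < lower <= upper < 1", call. = FALSE)
  lo <- round(lower * 100); hi <- round(upper * 100); st <- round(step * 100)
  if (st <= 0 || (hi - lo) %% st != 0)
    stop("step must be positive and divide the bound range", call. = FALSE)
  structure(list(n_levels = as.integer(n_levels), lower_pct = lo,
                 upper_pct = hi, step_pct = st), class = "grid_spec")
}

#' Enumerate admissible educational-level distributions
#'
#' Runs the free shares (all levels but the last) over the step grid, sets
#' the last share to the complement to 100%, and keeps exactly the
#' combinations where every share lies within the bounds (inclusive). The
#' result is in deterministic lexicographic order of the free shares.
#'
#' With the default 4-level spec (bounds 5-50%, step 5 points) the
#' enumeration yields 633 admissible combinations.
#'
#' @param spec A [grid_spec()].
#' @return Data frame of integer percents, columns `p1` ... `p<n>`, one row
#'   per admissible combination; zero rows when the grid is infeasible.
#' @examples
#' nrow(generate_eld_grid(grid_spec()))  # 633
#' @export
generate_eld_grid <- function(spec = grid_spec()) {
  stopifnot(inherits(spec, "grid_spec"))
  n <- spec$n_levels
  vals <- seq.int(spec$lower_pct, spec$upper_pct, by = spec$step_pct)
  free <- rev(expand.grid(rep(list(vals), n - 1L))[, (n - 1L):1, drop = FALSE])
  names(free) <- paste0("p", seq_len(n - 1L))
  last <- 100L - rowSums(free)
  keep <- last >= spec$lower_pct & last <= spec$upper_pct
  out <- free[keep, , drop = FALSE]
  out[[paste0("p", n)]] <- last[keep]
  out <- out[do.call(order, out[seq_len(n - 1L)]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate inequality indices over a distribution grid
#'
#' Computes the SII, RII and PAF for every distribution of the grid, holding
#' the rate schedule fixed across all of them.
#'
#' @param grid Data frame of integer-percent shares as produced by
#'   [generate_eld_grid()].
#' @param rates Rate schedule (per 100,000 person-years), one rate per level.
#' @param reference Reference level for the PAF; defaults to the last level.
#' @return The grid with `sii`, `rii` and `paf` columns appended.
#' @examples
#' g <- evaluate_grid(generate_eld_grid(grid_spec()), belgium_rates_2001())
#' head(g)
#' @export
evaluate_grid <- function(grid, rates, reference = length(rates)) {
  share_cols <- grep("^p[0-9]+$", names(grid), value = TRUE)
  if (length(share_cols) != length(rates))
    stop("schedule has ", length(rates), " rates but the grid has ",
         length(share_cols), " share columns", call. = FALSE)
  m <- as.matrix(grid[share_cols]) / 100
  res <- t(apply(m, 1L, function(p) {
    ix <- inequality_indices(p, rates, reference)
    c(ix$sii, ix$rii, ix$paf)
  }))
  grid$sii <- res[, 1]; grid$rii <- res[, 2]; grid$paf <- res[, 3]
  grid
}

#' Extract an index-versus-p4 curve family from an evaluated grid
#'
#' A curve family fixes two of the first three shares and follows one index
#' as the top share p4 grows, the remaining share varying as the complement.
#' The three kinds match the simulation's plotted panels:
#' `"fixed_p2p3"` (p1 varies in complement to p4), `"fixed_p1p3"` (p2
#' varies) and `"fixed_p1p2"` (p3 varies).
#'
#' @param result Evaluated grid from [evaluate_grid()] (4 levels).
#' @param kind One of `"fixed_p2p3"`, `"fixed_p1p3"`, `"fixed_p1p2"`.
#' @param fixed Integer-percent values of the two fixed shares, in the order
#'   named by `kind` (e.g. `c(p2 = 25, p3 = 25)` for `"fixed_p2p3"`).
#' @param index Which index the family tracks: `"sii"`, `"rii"` or `"paf"`.
#' @param absolute Track the absolute value of the index (conventional for
#'   the SII, whose sign is negative for adverse gradients)?
#' @return Data frame of class `"curve_family"`, ordered by `p4`, with the
#'   share columns and a `value` column; zero rows if the fixed values miss
#'   the lattice.
#' @export
extract_family <- function(result, kind = c("fixed_p2p3", "fixed_p1p3", "fixed_p1p2"),
                           fixed, index = c("rii", "sii", "paf"),
                           absolute = NULL) {
  kind <- match.arg(kind)
  index <- match.arg(index)
  if (is.null(absolute)) absolute <- index == "sii"
  stopifnot(length(fixed) == 2L, all(c("p4", index) %in% names(result)))
  fixed_cols <- switch(kind,
                       fixed_p2p3 = c("p2", "p3"),
                       fixed_p1p3 = c("p1", "p3"),
                       fixed_p1p2 = c("p1", "p2"))
  keep <- result[[fixed_cols[1]]] == round(fixed[1]) &
          result[[fixed_cols[2]]] == round(fixed[2])
  fam <- result[keep, , drop = FALSE]
  fam <- fam[order(fam$p4), , drop = FALSE]
  fam$value <- if (absolute) abs(fam[[index]]) else fam[[index]]
  rownames(fam) <- NULL
  structure(fam, class = c("curve_family", "data.frame"),
            kind = kind, fixed = setNames(round(fixed), fixed_cols),
            index = index, absolute = absolute)
}

#' Locate the extremum of a curve family
#'
#' Returns the p4 at which the family's tracked value (absolute index value
#' when the family was extracted with `absolute = TRUE`) is largest. Ties are
#' broken toward the smaller p4.
#'
#' @param family A [extract_family()] result with at least one point.
#' @return List with `p4` (integer percent) and `value` at the maximum.
#' @export
find_maximum <- function(family) {
  stopifnot(inherits(family, "curve_family"))
  if (nrow(family) == 0L) stop("empty curve family", call. = FALSE)
  v <- abs(family$value)
  i <- which(v == max(v))[1]          # rows are p4-ordered: first = smallest p4
  list(p4 = family$p4[i], value = family$value[i])
}

#' Check strict monotonicity of a curve family
#'
#' @param family A [extract_family()] result with at least two points.
#' @param direction `"increasing"` or `"decreasing"`.
#' @return List with `monotone` (logical) and `first_violation` (the p4 at
#'   which the first non-conforming step ends, or `NA`).
#' @export
check_monotone <- function(family, direction = c("increasing", "decreasing")) {
  stopifnot(inherits(family, "curve_family"))
  direction <- match.arg(direction)
  if (nrow(family) < 2L) stop("need at least 2 points", call. = FALSE)
  d <- diff(family$value)
  bad <- if (direction == "increasing") which(d <= 0) else which(d >= 0)
  list(monotone = length(bad) == 0L,
       first_violation = if (length(bad)) family$p4[bad[1] + 1L] else NA_integer_)
}

#' Filter grid records by statistical significance of SII and RII
#'
#' Rebuilds each grid record as a stratified population of
#' `total_person_years` person-years with expected (noise-free) death counts
#' under the schedule, computes analytic confidence intervals for the SII
#' and RII (see [indices_with_ci()]), and retains only the records whose SII
#' interval excludes 0 and whose RII interval excludes 1.
#'
#' The retained count depends on the interval method and on the person-years
#' supplied; both are explicit arguments rather than hidden constants.
#'
#' @param result Evaluated grid from [evaluate_grid()].
#' @param rates Rate schedule used to evaluate the grid.
#' @param total_person_years Person-years of the whole population behind each
#'   record (required).
#' @param ci_level Confidence level (default 0.95).
#' @return The subset of `result` passing the filter, with `sii_lo`,
#'   `sii_hi`, `rii_lo`, `rii_hi` columns appended.
#' @export
filter_by_significance <- function(result, rates, total_person_years,
                                   ci_level = 0.95) {
  if (missing(total_person_years) || !is.finite(total_person_years) ||
      total_person_years <= 0)
    stop("total_person_years must be a positive number", call. = FALSE)
  share_cols <- grep("^p[0-9]+$", names(result), value = TRUE)
  ci <- t(apply(as.matrix(result[share_cols]) / 100, 1L, function(p) {
    pop <- expected_counts(p, rates, total_person_years)
    est <- indices_with_ci(pop, ci_level)
    c(est$ci["sii", ], est$ci["rii", ])
  }))
  colnames(ci) <- c("sii_lo", "sii_hi", "rii_lo", "rii_hi")
  out <- cbind(result, as.data.frame(ci))
  keep <- (out$sii_lo > 0 | out$sii_hi < 0) & (out$rii_lo > 1 | out$rii_hi < 1)
  keep[is.na(keep)] <- FALSE
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
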