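# Independent oracles used across tests.

# Brute-force triple-loop enumeration of admissible 4-level share lattices,
# independent of the package's expand.grid-based generator.
oracle_grid4 <- function(lo = 5, hi = 50, step = 5) {
  out <- NULL
  for (p1 in seq(lo, hi, step))
    for (p2 in seq(lo, hi, step))
      for (p3 in seq(lo, hi, step)) {
        p4 <- 100 - p1 - p2 - p3
        if (p4 >= lo && p4 <= hi)
          out <- rbind(out, c(p1, p2, p3, p4))
      }
  colnames(out) <- paste0("p", 1:4)
  as.data.frame(out)
}

# Generic weighted-least-squares slope via lm(), the reference for the
# closed-form covariance-ratio slope.
oracle_wls <- function(x, y, w) {
  fit <- stats::lm(y ~ x, weights = w)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       fit = fit)
}

# Random valid distribution on n levels (strictly positive, sums to 1).
random_eld <- function(n) {
  p <- stats::runif(n, 0.05, 1)
  p / sum(p)
}

# Canonical study inputs.
eld1 <- c(0.40, 0.25, 0.25, 0.10)
eld2 <- c(0.20, 0.25, 0.25, 0.30)
rates1 <- c(750, 550, 450, 300)
rates2 <- c(630, 500, 400, 290)
rates3 <- c(750, 570, 420, 260)
belgian <- c(733.8, 552.1, 450.1, 313.9)
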