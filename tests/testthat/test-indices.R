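# Published comparison-table values for the study scenarios: the slope index
# reproduces to the printed integer, RII and PAF to 2 decimals.
test_that("SII, RII and PAF reproduce the published scenario values", {
  cases <- list(
    list(p = eld1, y = rates1, sii = -559, rii = 2.86, paf = 0.48),  # A
    list(p = eld2, y = rates1, sii = -567, rii = 3.75, paf = 0.39),  # B
    list(p = eld2, y = rates2, sii = -441, rii = 3.03, paf = 0.34)   # D
  )
  for (cs in cases) {
    expect_equal(round(sii(cs$p, cs$y)), cs$sii)
    expect_equal(round(rii(cs$p, cs$y), 2), cs$rii)
    expect_equal(round(paf(cs$p, cs$y), 2), cs$paf)
  }
  # scenario C: the printed SII is consistent with its inputs
  expect_equal(round(sii(eld1, rates2)), -424)
  # unrounded anchors
  expect_equal(sii(eld1, rates1), -559.3, tolerance = 1e-3)
  expect_equal(sii(eld2, rates1), -567.1, tolerance = 1e-3)
  expect_equal(sii(eld1, rates2), -423.9, tolerance = 1e-3)
  expect_equal(paf(eld1, rates1), 0.4828, tolerance = 1e-4)
  expect_equal(paf(eld2, rates2), 0.3379, tolerance = 1e-4)
})

test_that("constant rates give SII 0, RII 1, PAF 0", {
  set.seed(11)
  for (rep in 1:10) {
    p <- random_eld(sample(2:6, 1))
    c0 <- stats::runif(1, 50, 900)
    y <- rep(c0, length(p))
    expect_equal(sii(p, y), 0, tolerance = 1e-12)
    expect_equal(rii(p, y), 1, tolerance = 1e-12)
    expect_equal(paf(p, y), 0, tolerance = 1e-12)
  }
})

test_that("closed-form SII matches a generic weighted least-squares solver", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(2:8, 1)
    p <- random_eld(n)
    y <- stats::runif(n, 10, 1000)
    o <- oracle_wls(ridit_scores(p), y, p)
    expect_equal(sii(p, y), o$slope, tolerance = 1e-9)
    ix <- inequality_indices(p, y)
    expect_equal(ix$intercept, o$intercept, tolerance = 1e-9)
    # RII equals the ratio of fitted values at rank 0 and rank 1
    pred <- stats::predict(o$fit, newdata = data.frame(x = c(0, 1)))
    if (pred[2] > 0)
      expect_equal(ix$rii, unname(pred[1] / pred[2]), tolerance = 1e-9)
  }
})

test_that("translation and scaling act on the indices as expected", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    p <- random_eld(n)
    y <- sort(stats::runif(n, 100, 900), decreasing = TRUE)
    k <- stats::runif(1, 0.5, 3)
    cshift <- stats::runif(1, 10, 200)
    ix <- inequality_indices(p, y)
    # adding a constant: slope unchanged, intercept shifts by the constant
    ix_t <- inequality_indices(p, y + cshift)
    expect_equal(ix_t$sii, ix$sii, tolerance = 1e-9)
    expect_equal(ix_t$intercept, ix$intercept + cshift, tolerance = 1e-9)
    # scaling: slope scales, RII and PAF invariant
    ix_s <- inequality_indices(p, k * y)
    expect_equal(ix_s$sii, k * ix$sii, tolerance = 1e-9)
    expect_equal(ix_s$rii, ix$rii, tolerance = 1e-9)
    expect_equal(ix_s$paf, ix$paf, tolerance = 1e-9)
  }
})

test_that("PAF lies in [0, 1) when the top level has the lowest positive rate", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    p <- random_eld(n)
    y <- sort(stats::runif(n, 50, 900), decreasing = TRUE)
    v <- paf(p, y)
    expect_gte(v, 0)
    expect_lt(v, 1)
  }
})

test_that("pairwise differentials match the published block and ignore shares", {
  pw <- pairwise_rates(rates2)
  expect_equal(pw$difference[1], 340)
  expect_equal(round(pw$ratio[1], 2), 2.17)
  pw3 <- pairwise_rates(rates3)
  expect_equal(pw3$difference[1], 490)
  expect_equal(round(pw3$ratio[1], 2), 2.88)
  # reference vs itself
  expect_equal(pw$difference[4], 0)
  expect_equal(pw$ratio[4], 1)
  # zero reference rate: ratio undefined, difference still there
  pw0 <- pairwise_rates(c(100, 0))
  expect_true(is.na(pw0$ratio[1]))
  expect_equal(pw0$difference[1], 100)
  expect_error(pairwise_rates(rates1, reference = 9), "out of range")
})

test_that("bundled indices are internally consistent", {
  ix <- inequality_indices(eld1, rates1)
  expect_equal(ix$rii, ix$intercept / ix$fitted_top, tolerance = 1e-12)
  expect_equal(ix$fitted_top, ix$intercept + ix$sii, tolerance = 1e-12)
  expect_equal(ix$paf, (ix$mean_rate - rates1[4]) / ix$mean_rate,
               tolerance = 1e-12)
  expect_equal(ix$mean_rate, sum(eld1 * rates1), tolerance = 1e-12)
  disp <- format(ix)
  expect_equal(disp[["sii"]], "-559")
  expect_equal(disp[["rii"]], "2.86")
  expect_equal(disp[["paf"]], "0.48")
})

test_that("a non-positive fitted top rate is an error, not a clamp", {
  # steep gradient: fitted value at rank 1 goes negative
  expect_error(rii(c(0.5, 0.5), c(2000, 10)), "top of the rank scale")
  # bundled computation reports NA instead
  ix <- inequality_indices(c(0.5, 0.5), c(2000, 10))
  expect_true(is.na(ix$rii))
})

test_that("two-level inputs reduce to the weighted two-point slope", {
  p <- c(0.3, 0.7)
  y <- c(800, 400)
  x <- ridit_scores(p)
  expect_equal(sii(p, y), (y[2] - y[1]) / (x[2] - x[1]), tolerance = 1e-9)
})
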