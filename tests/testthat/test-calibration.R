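# In the limit of vanishing diversification the calibration density has the
# closed form psi * exp(-psi * (t - t_f)): a single lineage accumulates
# S = t - t_f deterministically.

test_that("vanishing-diversification limit recovers the exponential form", {
  bd <- BDParams(1e-9, 0, 0.05)
  d <- singleCalibrationDensity(bd, FossilRecord("f", 100), nReps = 1e5,
                                seed = 1)
  g <- ageGrid(d)
  expect_lt(max(abs(densityValues(d) - 0.05 * exp(-0.05 * (g - 100)))),
            0.003)
  expect_equal(g[1L], 100)
})

test_that("density is zero below the fossil's minimum age and normalised", {
  bd <- teleostBD()
  fossil <- FossilRecord("plec", 98.0, 100.3)
  d <- singleCalibrationDensity(bd, fossil, nReps = 3e4, seed = 2)
  expect_equal(evaluateDensity(d, c(0, 50, 97.9)), c(0, 0, 0))
  f <- densityValues(d)
  g <- ageGrid(d)
  integral <- sum(diff(g) * (f[-1L] + f[-length(f)]) / 2)
  expect_lt(abs(integral - 1), 0.01)
  # mode at or above the younger stratigraphic bound
  expect_gte(g[which.max(f)], 98.0)
})

test_that("invalid grids are rejected", {
  bd <- teleostBD()
  expect_error(singleCalibrationDensity(bd, FossilRecord("f", 100),
                                        gridSpec = list(grid = c(10, 20)),
                                        nReps = 100),
               "invalid grid")
  expect_error(singleCalibrationDensity(bd, FossilRecord("f", 100),
                                        gridSpec = list(grid = 5),
                                        nReps = 100),
               "invalid grid")
})

test_that("density kernel agrees with the naive per-lineage oracle", {
  lambda <- deriveRates(0.05, 0.2)$lambda
  mu <- deriveRates(0.05, 0.2)$mu
  psi <- 0.1
  bd <- BDParams(0.05, 0.2, psi)
  d <- singleCalibrationDensity(bd, FossilRecord("f", 10), nReps = 1e5,
                                seed = 3)
  set.seed(4)
  ages <- c(12, 15, 18, 22, 26, 30, 34, 38, 42, 46)
  brute <- t(vapply(ages, function(a)
    naiveKernel(lambda, mu, psi, a - 10, 3000), numeric(2L)))
  pkg <- evaluateDensity(d, ages)
  # the package density is normalised; fit the single scale factor and
  # compare pointwise within 3 brute-force standard errors
  cc <- sum(brute[, 1L] * pkg / brute[, 2L]^2) / sum(pkg^2 / brute[, 2L]^2)
  expect_true(all(abs(brute[, 1L] - cc * pkg) < 3 * brute[, 2L]))
})

test_that("mean clade age responds monotonically to the sampling rate", {
  means <- vapply(c(0.02, 0.05, 0.1), function(psi) {
    d <- singleCalibrationDensity(BDParams(0.05, 0.1, psi),
                                  FossilRecord("f", 50), nReps = 2e4,
                                  seed = 5)
    g <- ageGrid(d)
    f <- densityValues(d)
    sum(diff(g) * (g[-1L] * f[-1L] + g[-length(g)] * f[-length(f)]) / 2)
  }, numeric(1L))
  expect_true(all(diff(means) <= 0))
})

test_that("two-fossil mixture obeys the piecewise weighted-sum form", {
  bd <- teleostBD()
  cret <- FossilRecord("cret", 83.0, 89.8, weight = 2 / 3)
  plec <- FossilRecord("plec", 98.0, 100.3, weight = 1 / 3)
  d <- mixtureCalibrationDensity(cret, plec, bd, nReps = 3e4, seed = 6)
  comp <- densityComponents(d)
  expect_equal(unname(comp$weights), c(2 / 3, 1 / 3))
  g <- ageGrid(d)
  fy <- comp$younger[, "density"]
  fo <- comp$older[, "density"]
  expect_equal(densityValues(d), 2 / 3 * fy + 1 / 3 * fo, tolerance = 1e-12)
  # older component has no support below its own minimum age
  expect_true(all(fo[g < 98.0] == 0))
  # below the older fossil only the younger component contributes
  below <- g < 98.0
  expect_equal(densityValues(d)[below], (2 / 3 * fy)[below],
               tolerance = 1e-12)
  f <- densityValues(d)
  integral <- sum(diff(g) * (f[-1L] + f[-length(f)]) / 2)
  expect_lt(abs(integral - 1), 0.01)
})

test_that("degenerate mixture weights reduce to the single-fossil density", {
  bd <- BDParams(0.05, 0.1, 0.03)
  y <- FossilRecord("y", 60, weight = 1)
  o <- FossilRecord("o", 90, weight = 0)
  mix <- mixtureCalibrationDensity(y, o, bd, nReps = 2e4, seed = 7)
  single <- singleCalibrationDensity(bd, y, nReps = 2e4, seed = 7)
  expect_equal(ageGrid(mix), ageGrid(single))
  expect_equal(densityValues(mix), densityValues(single))
})

test_that("mixture weight validation and interval ordering work", {
  bd <- BDParams(0.05, 0.1, 0.03)
  expect_error(mixtureCalibrationDensity(
    FossilRecord("a", 60, weight = 0.6),
    FossilRecord("b", 90, weight = 0.6), bd, nReps = 100),
    "invalid weights")
  # swapped arguments are reordered by interval midpoint
  d1 <- mixtureCalibrationDensity(FossilRecord("o", 90, weight = 0.5),
                                  FossilRecord("y", 60, weight = 0.5),
                                  bd, nReps = 5e3, seed = 8)
  expect_equal(ageGrid(d1)[1L], 60)
  expect_warning(mixtureCalibrationDensity(
    FossilRecord("a", 60, 80, weight = 0.5),
    FossilRecord("b", 70, 95, weight = 0.5), bd, nReps = 5e3, seed = 9),
    "overlap")
})

test_that("widely separated point fossils give a bimodal density", {
  bd <- BDParams(0.061, 0.1856, 0.01233)
  mk <- function(sep) {
    mixtureCalibrationDensity(
      FossilRecord("y", 100, weight = 0.5),
      FossilRecord("o", 100 + sep, weight = 0.5), bd, nReps = 4e4,
      seed = 10)
  }
  far <- findDensityModes(mk(120))
  expect_true(far$bimodal)
  expect_length(far$modes[1:2], 2L)
})
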