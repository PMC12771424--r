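test_that("absorbanceAt interpolates linearly and hits grid points exactly", {
  sp <- Spectrum(c(500, 510, 520), c(0.1, 0.3, 0.2))
  expect_identical(absorbanceAt(sp, 510), 0.3)
  expect_equal(absorbanceAt(sp, 505), (0.1 + 0.3) / 2)
  expect_equal(absorbanceAt(sp, c(500, 515)), c(0.1, 0.25))
  expect_error(absorbanceAt(sp, 499), "span")
  expect_error(absorbanceAt(sp, 521), "span")
})

test_that("interpolated absorbance matches a closed-form Gaussian band", {
  wl <- seq(500, 600, by = 1)
  gauss <- function(x) exp(-4 * log(2) * ((x - 555) / 30)^2)
  sp <- Spectrum(wl, gauss(wl))
  q <- seq(520.5, 580.5, by = 1)  # off-grid queries
  expect_lt(max(abs(absorbanceAt(sp, q) - gauss(q))), 1e-3)
})

test_that("peak/trough ratio reads A555/A540", {
  flat <- Spectrum(seq(500, 600, 5), rep(0.42, 21), state = "ferrous-deoxy")
  expect_equal(peakTroughRatio(flat), 1.0)
  # constructed so that A(555) = 3.1 * A(540), the fully hexacoordinate ratio
  wl <- seq(538, 557, by = 1)
  a <- 1 + (3.1 - 1) / 15 * (wl - 540)
  expect_equal(peakTroughRatio(Spectrum(wl, a)), 3.1, tolerance = 1e-12)
  neg <- Spectrum(seq(500, 600, 5), rep(-0.1, 21))
  expect_error(peakTroughRatio(neg), "undefined")
})

test_that("mixture-spectrum ratio equals the basis-sum oracle", {
  b <- defaultBasisSpectra()
  sp <- equilibriumSpectrum(0.5, basis = b)
  oracle <- function(wl)
    0.5 * basisAbsorbance(b, "hexa_deoxy", wl) +
    0.5 * basisAbsorbance(b, "penta_deoxy", wl)
  expect_equal(peakTroughRatio(sp), oracle(555) / oracle(540),
               tolerance = 1e-12)
})

test_that("ratio -> F_H calibration anchors, midpoint and clamping", {
  cal <- defaultCalibration()
  expect_equal(ratioToFractionHexa(1.2, cal), 0)
  expect_equal(ratioToFractionHexa(3.1, cal), 1)
  expect_equal(ratioToFractionHexa(2.15, cal), 0.5)  # midpoint of the linear map
  expect_equal(ratioToFractionHexa(c(0.9, 5), cal), c(0, 1))  # clamps
  calM <- defaultCalibration(includeMaize = TRUE)
  expect_equal(ratioToFractionHexa(1.8, calM), 0.48)
})

test_that("ratio -> F_H is non-decreasing for any valid calibration", {
  set.seed(202)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    ratio <- sort(runif(n, 1, 4))
    fh <- sort(c(0, runif(n - 2), 1))
    cal <- CalibrationTable(ratio, fh)
    out <- ratioToFractionHexa(seq(0.5, 4.5, length.out = 200), cal)
    expect_true(all(diff(out) >= -1e-12))
  }
})

test_that("coordination equilibrium relation inverts as K_H = F_H/(1-F_H)", {
  expect_equal(round(fractionToKH(0.53), 1), 1.1)  # liverwort globin
  expect_equal(round(fractionToKH(0.48), 1), 0.9)  # maize Hb1
  expect_equal(fractionToKH(0.5), 1.0)
  expect_equal(fractionToKH(0), 0)
  expect_identical(fractionToKH(1), Inf)
  expect_error(fractionToKH(-0.1), "\\[0, 1\\]")
  expect_error(fractionToKH(1.1), "\\[0, 1\\]")
})

test_that("forward relation F_H = K_H/(1+K_H) and round trips", {
  expect_equal(kHToFraction(0), 0)
  expect_equal(kHToFraction(1), 0.5)
  expect_equal(kHToFraction(Inf), 1)
  expect_equal(round(kHToFraction(4.88), 2), 0.83)
  expect_error(kHToFraction(-1), ">= 0")
  f <- seq(0, 0.999, by = 0.001)
  expect_lt(max(abs(kHToFraction(fractionToKH(f)) - f)), 1e-12)
})

test_that("basis-built calibration recovers the generating F_H within 1e-3", {
  b <- defaultBasisSpectra()
  cal <- calibrationFromBasis(b)
  for (f in seq(0, 1, by = 0.1)) {
    sp <- equilibriumSpectrum(f, basis = b)
    est <- ratioToFractionHexa(peakTroughRatio(sp), cal)
    expect_lt(abs(est - f), 1e-3)
  }
})

test_that("full spectral pipeline reports (ratio, F_H, K_H) coherently", {
  b <- defaultBasisSpectra()
  cal <- calibrationFromBasis(b)
  res <- coordinationFromSpectrum(equilibriumSpectrum(0.83, basis = b), cal)
  expect_equal(res@fh, 0.83, tolerance = 1e-3)
  expect_equal(res@kH, res@fh / (1 - res@fh))
  expect_false(res@kHCapped)
  # fully hexacoordinate samples cap K_H with a warning
  expect_warning(
    capped <- coordinationFromSpectrum(equilibriumSpectrum(1, basis = b), cal),
    "cap")
  expect_true(capped@kHCapped)
  expect_identical(capped@kH, Inf)
})

test_that("calibration tables without boundary anchors are invalid", {
  expect_error(CalibrationTable(c(1.2, 3.1), c(0.1, 1)), "boundary")
  expect_error(CalibrationTable(c(3.1, 1.2), c(0, 1)), "increasing")
  expect_error(CalibrationTable(c(1.2, 2, 3.1), c(0, 0.9, 0.95)), "boundary")
})
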