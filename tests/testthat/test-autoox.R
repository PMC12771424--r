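test_that("time-course extraction interpolates each member spectrum", {
  b <- defaultBasisSpectra()
  ser <- autoxidationSeries(kOx = 0.52, duration = 5, nSpectra = 12, basis = b)
  tr <- extractTimecourse(ser, wavelength = 575)
  expect_identical(tr@timeUnit, "s")
  expect_equal(times(tr), vapply(ser, `[[`, numeric(1), "time") * 3600)
  # single-wavelength query equals absorbanceAt on each member spectrum
  expect_equal(signals(tr),
               vapply(ser, function(el) absorbanceAt(el$spectrum, 575),
                      numeric(1)))
  # and the noiseless trace is exactly offset + amplitude * exp(-k_ox t)
  oxy <- basisAbsorbance(b, "oxy", 575)
  fer <- basisAbsorbance(b, "ferric_hexa", 575)
  tH <- times(tr) / 3600
  expect_equal(signals(tr), fer + (oxy - fer) * exp(-0.52 * tH),
               tolerance = 1e-12)
})

test_that("a series of identical spectra gives a constant trace", {
  sp <- equilibriumSpectrum(0.5)
  ser <- lapply(0:8, function(i) list(time = i, spectrum = sp))
  tr <- extractTimecourse(ser, wavelength = 555)
  expect_equal(diff(range(signals(tr))), 0)
  expect_error(fitAutoox(tr), "failed")
})

test_that("extraction rejects bad series", {
  ser <- autoxidationSeries(kOx = 0.5, duration = 2, nSpectra = 5,
                            wavelengthGrid = seq(450, 650, 1))
  expect_error(extractTimecourse(ser[1:2]), ">= 3")
  expect_error(extractTimecourse(ser, wavelength = 700), "span")
})

test_that("autoxidation fit reports k_ox in 1/h and the matching half-life", {
  res <- fitAutoox(extractTimecourse(autoxidationSeries(0.88, duration = 4)))
  expect_equal(res@kOx, 0.88, tolerance = 1e-4)
  expect_equal(round(res@tHalf), 47)
  expect_equal(res@kOx * res@tHalf, 60 * log(2), tolerance = 1e-9)
  # definition of the half-life: k_ox = ln 2 per hour <-> 60 min
  expect_equal(autooxHalfLife(log(2)), 60)
  expect_equal(round(autooxHalfLife(c(0.88, 0.43, 0.52))), c(47, 97, 80))
})

test_that("seconds- and hours-labeled traces give the same k_ox", {
  b <- defaultBasisSpectra()
  tH <- seq(0, 5, length.out = 20)
  a575 <- basisAbsorbance(b, "ferric_hexa", 575) +
    (basisAbsorbance(b, "oxy", 575) - basisAbsorbance(b, "ferric_hexa", 575)) *
    exp(-0.43 * tH)
  rS <- fitAutoox(KineticTrace(tH * 3600, a575, timeUnit = "s"))
  rH <- fitAutoox(KineticTrace(tH, a575, timeUnit = "h"))
  expect_equal(rS@kOx, rH@kOx, tolerance = 1e-9)
  expect_equal(rS@kOx, 0.43, tolerance = 1e-6)
})

test_that("noisy autoxidation series recovers k_ox within 5%", {
  # 2% of the trace amplitude (~0.30 AU) as Gaussian sd, fixed seed
  ser <- autoxidationSeries(0.43, duration = 7, nSpectra = 40,
                            noise = NoiseModel(sd = 0.006, seed = 11L))
  res <- fitAutoox(extractTimecourse(ser))
  expect_lt(abs(res@kOx - 0.43) / 0.43, 0.05)
})

test_that("the literature comparison table is static and unit-checked", {
  ref <- autooxReferenceTable()
  expect_setequal(c("protein", "kOx_per_h", "tHalf_min", "conditions"),
                  names(ref))
  # consistent rows satisfy the half-life identity; the two known
  # source-table discrepancies (At nsHb1, Ngb) are carried as printed
  consistent <- abs(ref$kOx_per_h * ref$tHalf_min - 60 * log(2)) <
    0.05 * 60 * log(2)
  expect_identical(ref$protein[!consistent], c("At nsHb1", "Ngb"))
})
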