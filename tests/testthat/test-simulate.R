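test_that("flash-photolysis rebinding relaxes at k'[L] + k_off", {
  # His rebinding disabled; air-equilibrated O2
  tr <- flashPhotolysisTrace(physScheme(), "O2", conc = 262)
  expected <- 148 * 262 + 5.2
  expect_equal(tr@meta$trueRate, expected)
  fit <- fitSingleExponential(tr)
  expect_true(fit@accepted)
  expect_lt(abs(fit@kObs - expected) / expected, 0.001)
})

test_that("zero amplitude scale gives an identically zero trace", {
  tr <- flashPhotolysisTrace(physScheme(), "O2", conc = 262, scale = 0)
  expect_identical(unique(signals(tr)), 0)
})

test_that("identical seeds reproduce identical noisy traces", {
  nm <- NoiseModel(sd = 0.01, seed = 7L)
  t1 <- flashPhotolysisTrace(physScheme(), "O2", conc = 262, noise = nm)
  t2 <- flashPhotolysisTrace(physScheme(), "O2", conc = 262, noise = nm)
  expect_identical(signals(t1), signals(t2))
  t3 <- flashPhotolysisTrace(physScheme(), "O2", conc = 262,
                             noise = NoiseModel(sd = 0.01, seed = 8L))
  expect_false(identical(signals(t1), signals(t3)))
  # equilibrium spectra obey the same determinism contract
  s1 <- equilibriumSpectrum(0.5, noise = nm)
  s2 <- equilibriumSpectrum(0.5, noise = nm)
  expect_identical(absorbances(s1), absorbances(s2))
})

test_that("stopped-flow displacement with no O2 relaxes at k_O2,off", {
  tr <- stoppedFlowDisplacementTrace(physScheme(), o2Conc = 0, coConc = 1000)
  fit <- fitSingleExponential(tr)
  expect_lt(abs(fit@kObs - 5.2) / 5.2, 0.01)
})

test_that("O2/CO competition slows the displacement to the predicted rate", {
  # arithmetic oracle: k_obs = k_O2,off / (1 + k'_O2 [O2] / (k'_CO [CO]))
  kAsym <- 5.2 / (1 + 148 * 56.2 / (0.58 * 1000))
  tr <- stoppedFlowDisplacementTrace(physScheme(), o2Conc = 56.2, coConc = 1000)
  expect_equal(tr@meta$trueRate, kAsym, tolerance = 1e-12)
  fit <- fitSingleExponential(tr)
  expect_lt(abs(fit@kObs - kAsym) / kAsym, 0.01)
  expect_equal(round(fit@kObs, 2), 0.34)  # the fitted moss-globin value
})

test_that("displacement rate depends only on the [O2]/[CO] ratio", {
  t1 <- stoppedFlowDisplacementTrace(physScheme(), o2Conc = 56.2, coConc = 1000)
  t2 <- stoppedFlowDisplacementTrace(physScheme(), o2Conc = 112.4, coConc = 2000)
  expect_equal(t1@meta$trueRate, t2@meta$trueRate, tolerance = 1e-12)
  f1 <- fitSingleExponential(t1)
  f2 <- fitSingleExponential(t2)
  expect_lt(abs(f1@kObs - f2@kObs) / f1@kObs, 0.01)
})

test_that("equilibrium spectra are exact basis mixtures at the boundaries", {
  b <- defaultBasisSpectra()
  wl <- seq(450, 650, by = 1)
  s0 <- equilibriumSpectrum(0, basis = b, wavelengthGrid = wl)
  expect_equal(absorbances(s0), basisAbsorbance(b, "penta_deoxy", wl))
  s1 <- equilibriumSpectrum(1, basis = b, wavelengthGrid = wl)
  expect_equal(absorbances(s1), basisAbsorbance(b, "hexa_deoxy", wl))
  expect_error(equilibriumSpectrum(1.2), "\\[0, 1\\]")
})

test_that("autoxidation series follows exp(-k_ox t) exactly when noiseless", {
  b <- defaultBasisSpectra()
  ser <- autoxidationSeries(kOx = 0.88, duration = 4, nSpectra = 9, basis = b)
  wl <- wavelengths(ser[[1]]$spectrum)
  oxy <- basisAbsorbance(b, "oxy", wl)
  fer <- basisAbsorbance(b, "ferric_hexa", wl)
  # t = 0 spectrum is the oxy basis
  expect_equal(absorbances(ser[[1]]$spectrum), oxy)
  # closed form at the final time
  fEnd <- exp(-0.88 * 4)
  expect_equal(absorbances(ser[[9]]$spectrum), fEnd * oxy + (1 - fEnd) * fer,
               tolerance = 1e-12)
  expect_error(autoxidationSeries(0.88, duration = -1), "positive")
  expect_error(autoxidationSeries(-0.1, duration = 1), "positive")
})

test_that("noiseless autoxidation round trip recovers k_ox to 0.1%", {
  ser <- autoxidationSeries(kOx = 0.88, duration = 4)
  res <- fitAutoox(extractTimecourse(ser, wavelength = 575))
  expect_lt(abs(res@kOx - 0.88) / 0.88, 0.001)
})

test_that("monitor wavelengths outside the rendered span are rejected", {
  expect_error(flashPhotolysisTrace(physScheme(), "O2", conc = 262,
                                    monitorWavelength = 900), "span")
  expect_error(stoppedFlowDisplacementTrace(physScheme(), o2Conc = 0,
                                            coConc = 100,
                                            monitorWavelength = 100), "span")
  expect_error(flashPhotolysisTrace(physScheme(), "O2", conc = 0), "positive")
  expect_error(stoppedFlowDisplacementTrace(physScheme(), o2Conc = 10,
                                            coConc = 0), "positive")
})
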