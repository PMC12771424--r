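makeTrace <- function(time, signal, ...) KineticTrace(time, signal, ...)

test_that("replicate averaging is pointwise and marks the result", {
  tt <- seq(0, 10, length.out = 50)
  y <- 0.3 * exp(-0.5 * tt)
  tr <- makeTrace(tt, y)
  one <- averageTraces(list(tr))
  expect_equal(signals(one), y)
  expect_identical(one@replicateId, "averaged")
  # a trace and its negation cancel
  avg <- averageTraces(list(tr, makeTrace(tt, -y)))
  expect_equal(signals(avg), rep(0, 50))
  # mismatched grids are rejected
  expect_error(averageTraces(list(tr, makeTrace(tt + 0.1, y))), "share")
})

test_that("averaging 10 seeded replicates shrinks residual noise ~ sqrt(10)", {
  tt <- seq(0, 10, length.out = 400)
  y0 <- 0.3 * exp(-0.5 * tt)
  reps <- lapply(1:10, function(r)
    makeTrace(tt, y0 + withr::with_seed(300 + r, rnorm(400, 0, 0.02))))
  avg <- averageTraces(reps)
  sdOne <- sd(signals(reps[[1]]) - y0)
  sdAvg <- sd(signals(avg) - y0)
  expect_gt(sdOne / sdAvg, 2)      # ~ sqrt(10) = 3.16, allow sampling spread
  expect_lt(sdOne / sdAvg, 4.5)
})

test_that("single-exponential fit recovers a noiseless decay to 1e-6", {
  tt <- seq(0, 20, length.out = 120)
  fit <- fitSingleExponential(makeTrace(tt, 0.2 * exp(-0.34 * tt)))
  expect_true(fit@accepted)
  expect_equal(fit@kObs, 0.34, tolerance = 1e-6)
  expect_equal(fit@amplitude, 0.2, tolerance = 1e-6)
  expect_equal(fit@offset, 0, tolerance = 1e-8)
})

test_that("single-exponential fit handles offsets, recoveries and noise", {
  tt <- seq(0, 15, length.out = 200)
  # decay onto a nonzero baseline
  f1 <- fitSingleExponential(makeTrace(tt, 0.5 + 0.2 * exp(-0.7 * tt)))
  expect_equal(f1@kObs, 0.7, tolerance = 1e-6)
  expect_equal(f1@offset, 0.5, tolerance = 1e-6)
  # rising recovery (negative amplitude)
  f2 <- fitSingleExponential(makeTrace(tt, 0.5 - 0.2 * exp(-0.7 * tt)))
  expect_equal(f2@kObs, 0.7, tolerance = 1e-6)
  expect_equal(f2@amplitude, -0.2, tolerance = 1e-6)
  # 2% noise: rate within 5% of truth
  y <- 0.2 * exp(-0.34 * seq(0, 20, length.out = 300))
  yn <- y + withr::with_seed(42, rnorm(300, 0, 0.02 * 0.2))
  f3 <- fitSingleExponential(makeTrace(seq(0, 20, length.out = 300), yn))
  expect_lt(abs(f3@kObs - 0.34) / 0.34, 0.05)
})

test_that("a constant trace yields a degenerate fit, never a rate", {
  fit <- fitSingleExponential(makeTrace(seq(0, 10, 1), rep(0.7, 11)))
  expect_true(fit@degenerate)
  expect_identical(fit@amplitude, 0)
  expect_true(is.na(fit@kObs))
  expect_false(fit@accepted)
})

test_that("bimolecular rate from concentration dependence", {
  # exact line through the moss-globin CO rate: slope 0.58, intercept 0
  br <- bimolecularRate(c(100, 1000), c(58, 580))
  expect_equal(br$kPrime, 0.58, tolerance = 1e-12)
  expect_equal(br$kOffIntercept, 0, tolerance = 1e-9)
  expect_identical(br$method, "regression")
  # single-point design with supplied k_off
  br1 <- bimolecularRate(262, 38781.2, kOff = 5.2)
  expect_equal(br1$kPrime, (38781.2 - 5.2) / 262)
  expect_identical(br1$method, "single-point")
  expect_error(bimolecularRate(c(100, 100), c(58, 59)), "kOff")
  # negative intercepts are reported with a warning, not clamped
  expect_warning(br2 <- bimolecularRate(c(1, 2, 3), c(0.5, 2, 3.5)),
                 "negative intercept")
  expect_lt(br2$kOffIntercept, 0)
})

test_that("regression recovers a noisy true line within 2 standard errors", {
  set.seed(77)
  conc <- c(100, 250, 500, 750, 1000)
  kObs <- 0.58 * conc + 3 + rnorm(5, 0, 5)
  br <- bimolecularRate(conc, kObs)
  expect_lt(abs(br$kPrime - 0.58), 2 * br$seKPrime)
})

test_that("competition correction reproduces the arithmetic oracle", {
  # oracle: k_O2 = k_obs * (1 + k'_O2 [O2] / (k'_CO [CO]))
  kO2 <- correctO2Dissociation(0.34, 148, 0.58, o2Conc = 56.2, coConc = 1000)
  expect_equal(kO2, 0.34 * (1 + 148 * 56.2 / (0.58 * 1000)), tolerance = 1e-15)
  expect_equal(round(kO2, 1), 5.2)  # the printed dissociation rate
  # [O2] = 0 limit returns k_obs unchanged
  expect_identical(correctO2Dissociation(0.34, 148, 0.58, 0, 1000), 0.34)
  # depends only on the concentration ratio
  expect_equal(correctO2Dissociation(0.34, 148, 0.58, 112.4, 2000), kO2)
  expect_error(correctO2Dissociation(0.34, 148, 0.58, 56.2, 0), "coConc")
  expect_error(correctO2Dissociation(-0.1, 148, 0.58, 56.2, 1000), ">= 0")
})

test_that("competition correction is monotone and >= k_obs", {
  set.seed(33)
  for (i in 1:50) {
    kObs <- runif(1, 0.01, 5); kpO2 <- runif(1, 1, 300)
    kpCO <- runif(1, 0.1, 10); o2 <- runif(1, 0, 300); co <- runif(1, 1, 2000)
    v <- correctO2Dissociation(kObs, kpO2, kpCO, o2, co)
    # brute-force recomputation
    expect_equal(v, kObs * (1 + kpO2 * o2 / (kpCO * co)), tolerance = 1e-15)
    expect_gte(v, kObs)
    # monotone non-decreasing in [O2], non-increasing in [CO]
    expect_gte(correctO2Dissociation(kObs, kpO2, kpCO, o2 * 1.5, co), v)
    expect_lte(correctO2Dissociation(kObs, kpO2, kpCO, o2, co * 1.5), v)
  }
})

test_that("binding constants combine rates and K_H per the affinity relation", {
  b <- bindingConstants(148, 5.2, kH = fractionToKH(0.83))
  expect_equal(signif(b@kO2Pent, 2), 28)
  expect_equal(signif(b@kO2Eq, 2), 4.8)
  expect_identical(b@kO2PentSource, "rates")
  # direct K_O2,pent override (published unrounded intermediates)
  b2 <- bindingConstants(208, 7.5, kH = 1, kO2PentOverride = 30)
  expect_equal(b2@kO2Eq, 15)
  expect_identical(b2@kO2PentSource, "override")
  # pentacoordinate limit: K_H = 0 leaves the affinity uncorrected
  b3 <- bindingConstants(148, 5.2, kH = 0)
  expect_equal(b3@kO2Eq, b3@kO2Pent)
  # brute-force identity on random inputs
  set.seed(55)
  for (i in 1:25) {
    kp <- runif(1, 10, 300); ko <- runif(1, 0.5, 10); kh <- runif(1, 0, 20)
    bi <- bindingConstants(kp, ko, kH = kh)
    expect_equal(bi@kO2Pent, kp / ko, tolerance = 1e-15)
    expect_equal(bi@kO2Eq, (kp / ko) / (1 + kh), tolerance = 1e-15)
  }
  expect_error(bindingConstants(148, 0, kH = 1), "> 0")
  expect_error(bindingConstants(148, 5.2, kH = -1), ">= 0")
})
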