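# Shared fixtures: random kinetic schemes and the independent
# matrix-exponential oracle for the linear mass-action system.

randomScheme <- function() {
  KineticScheme(kHOn = runif(1, 0, 5), kHOff = runif(1, 0.1, 5),
                kPrimeO2 = runif(1, 0, 2), kO2Off = runif(1, 0, 5),
                kPrimeCO = runif(1, 0, 2), kCOOff = runif(1, 0, 5))
}

randomFractions <- function() {
  x <- runif(4)
  x <- x / sum(x)
  names(x) <- c("hexa", "penta", "oxy", "co")
  x
}

# Independent oracle: x(t) = expm(A t) x0 for the same linear system.
expmTrajectory <- function(scheme, x0, o2Conc, coConc, times) {
  A <- HbKinetics:::.schemeRateMatrix(scheme, o2Conc, coConc)
  x0 <- x0[c("hexa", "penta", "oxy", "co")]
  t(vapply(times, function(t)
    as.numeric(Matrix::expm(A * t) %*% x0), numeric(4)))
}

# Rates used for the moss hemoglobin in examples throughout the suite.
physScheme <- function(kCOOff = 0) {
  KineticScheme(kPrimeO2 = 148, kO2Off = 5.2, kPrimeCO = 0.58,
                kCOOff = kCOOff)
}
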