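#' Simulate a flash-photolysis (transient absorption) rebinding trace
#'
#' Photolysis is treated as instantaneous and complete: at t = 0 the entire
#' heme pool is the pentacoordinate deoxy intermediate, and the trace follows
#' ligand rebinding (and, if enabled in the scheme, distal-His rebinding).
#' The signal is the absorbance change at the monitor wavelength relative to
#' the pre-flash, fully ligand-bound sample, rendered from the basis spectra,
#' plus optional Gaussian noise.
#'
#' With His rebinding disabled (`kHOn = 0`) and a single ligand the
#' relaxation is exactly single-exponential with rate
#' `k' * [L] + k_off`; that true rate is stored in `meta$trueRate`.
#'
#' @param scheme a [KineticScheme-class].
#' @param ligand `"O2"` or `"CO"`.
#' @param conc ligand concentration in uM, > 0.
#' @param monitorWavelength nm, within the rendered 350-700 nm span.
#' @param basis a [BasisSpectra-class].
#' @param noise a [NoiseModel-class].
#' @param timeGrid times in s; defaults to 7 half-lives of the expected
#'   pseudo-first-order rate.
#' @param scale overall signal amplitude scale (optical path/concentration
#'   factor); 0 gives an identically zero trace.
#' @return a [KineticTrace-class] (delta-OD vs s).
#' @examples
#' sch <- KineticScheme(kPrimeO2 = 148, kO2Off = 5.2)
#' tr <- flashPhotolysisTrace(sch, "O2", conc = 262, monitorWavelength = 420)
#' tr@meta$trueRate  # 148*262 + 5.2
#' @export
flashPhotolysisTrace <- function(scheme, ligand = c("O2", "CO"), conc,
                                 monitorWavelength = 420,
                                 basis = defaultBasisSpectra(),
                                 noise = NoiseModel(), timeGrid = NULL,
                                 scale = 1) {
  ligand <- match.arg(ligand)
  stopifnot(is(scheme, "KineticScheme"))
  if (length(conc) != 1 || !is.finite(conc) || conc <= 0)
    stop("ligand concentration must be a single positive number", call. = FALSE)
  .checkMonitorWavelength(monitorWavelength)
  o2 <- if (ligand == "O2") conc else 0
  co <- if (ligand == "CO") conc else 0
  kOn <- if (ligand == "O2") scheme@kPrimeO2 else scheme@kPrimeCO
  kOff <- if (ligand == "O2") scheme@kO2Off else scheme@kCOOff
  trueRate <- kOn * conc + kOff + scheme@kHOn
  if (is.null(timeGrid)) {
    if (trueRate <= 0)
      stop("scheme has no rebinding dynamics; supply timeGrid explicitly",
           call. = FALSE)
    timeGrid <- relaxationTimeGrid(trueRate)
  }
  traj <- simulateScheme(scheme, c(penta = 1), o2Conc = o2, coConc = co,
                         timeGrid = timeGrid)
  eps <- .speciesAbsorbance(basis, monitorWavelength)
  boundState <- if (ligand == "O2") "oxy" else "co"
  refA <- eps[[boundState]]
  sig <- scale * (as.vector(traj@fractions %*% eps) - refA)
  sig <- .addNoise(sig, noise)
  KineticTrace(timeGrid, sig, monitorWavelength = monitorWavelength,
               o2Conc = o2, coConc = co, replicateId = "sim",
               meta = list(experiment = "flash_photolysis", ligand = ligand,
                           trueRate = trueRate, scale = scale))
}

#' Simulate a stopped-flow O2 -> CO displacement trace
#'
#' Models rapid 1:1 mixing of an oxyhemoglobin solution with CO-equilibrated
#' buffer: at t = 0 the heme pool is fully O2-bound, and the trace follows
#' conversion to the CO-bound state at the monitor wavelength. In the
#' CO-trapping regime (`kPrimeCO * coConc >> kCOOff`, His rebinding off) the
#' observed relaxation approaches
#' `kO2Off / (1 + kPrimeO2 * [O2] / (kPrimeCO * [CO]))`, i.e. the
#' displacement form of the competition correction; that asymptotic rate is
#' stored in `meta$trueRate`.
#'
#' @inheritParams flashPhotolysisTrace
#' @param o2Conc,coConc post-mix ligand concentrations in uM (`coConc > 0`).
#' @return a [KineticTrace-class] (delta-OD vs s, relative to the t = 0
#'   oxy sample).
#' @export
stoppedFlowDisplacementTrace <- function(scheme, o2Conc, coConc,
                                         monitorWavelength = 412,
                                         basis = defaultBasisSpectra(),
                                         noise = NoiseModel(), timeGrid = NULL,
                                         scale = 1) {
  stopifnot(is(scheme, "KineticScheme"))
  if (length(coConc) != 1 || !is.finite(coConc) || coConc <= 0)
    stop("coConc must be a single positive number", call. = FALSE)
  if (length(o2Conc) != 1 || !is.finite(o2Conc) || o2Conc < 0)
    stop("o2Conc must be a single non-negative number", call. = FALSE)
  .checkMonitorWavelength(monitorWavelength)
  denom <- scheme@kPrimeCO * coConc
  trueRate <- if (denom > 0)
    scheme@kO2Off / (1 + scheme@kPrimeO2 * o2Conc / denom) else scheme@kO2Off
  if (is.null(timeGrid)) {
    if (trueRate <= 0)
      stop("scheme has no displacement dynamics; supply timeGrid explicitly",
           call. = FALSE)
    timeGrid <- relaxationTimeGrid(trueRate, n = 400)
  }
  traj <- simulateScheme(scheme, c(oxy = 1), o2Conc = o2Conc, coConc = coConc,
                         timeGrid = timeGrid)
  eps <- .speciesAbsorbance(basis, monitorWavelength)
  sig <- scale * (as.vector(traj@fractions %*% eps) - eps[["oxy"]])
  sig <- .addNoise(sig, noise)
  KineticTrace(timeGrid, sig, monitorWavelength = monitorWavelength,
               o2Conc = o2Conc, coConc = coConc, replicateId = "sim",
               meta = list(experiment = "stopped_flow_displacement",
                           trueRate = trueRate, scale = scale))
}

#' Simulate an equilibrium ferrous-deoxy or ferric spectrum
#'
#' Renders a two-component coordination mixture on the requested grid:
#' `A = F_H * (hexa basis) + (1 - F_H) * (penta basis) + noise`, using the
#' ferrous-deoxy or ferric basis pair.
#'
#' @param fh fraction hexacoordinate, in `[0, 1]`.
#' @param state `"ferrous-deoxy"` or `"ferric"`.
#' @inheritParams flashPhotolysisTrace
#' @param wavelengthGrid wavelengths (nm), strictly increasing.
#' @return a [Spectrum-class].
#' @export
equilibriumSpectrum <- function(fh, state = c("ferrous-deoxy", "ferric"),
                                basis = defaultBasisSpectra(),
                                noise = NoiseModel(),
                                wavelengthGrid = seq(350, 700, by = 1)) {
  state <- match.arg(state)
  if (length(fh) != 1 || !is.finite(fh) || fh < 0 || fh > 1)
    stop("fh must be a single number in [0, 1]", call. = FALSE)
  pair <- if (state == "ferrous-deoxy") c("hexa_deoxy", "penta_deoxy")
          else c("ferric_hexa", "ferric_penta")
  a <- fh * basisAbsorbance(basis, pair[1], wavelengthGrid) +
    (1 - fh) * basisAbsorbance(basis, pair[2], wavelengthGrid)
  a <- .addNoise(a, noise)
  Spectrum(wavelengthGrid, a, state = state,
           sampleId = sprintf("sim F_H=%g", fh))
}

#' Simulate an autoxidation spectral series
#'
#' The oxy complex decays exponentially to the ferric state:
#' each spectrum is `f(t) * (oxy basis) + (1 - f(t)) * (ferric basis)` with
#' `f(t) = exp(-kOx * t)`, plus optional Gaussian noise. Times are in hours.
#' The ferric end state uses the hexacoordinate ferric basis (hexacoordinate
#' globins are bis-histidyl in the ferric resting state).
#'
#' @param kOx autoxidation rate constant in h^-1, > 0.
#' @param duration total duration in h, > 0.
#' @param nSpectra number of spectra (>= 3), evenly spaced from 0 to
#'   `duration`.
#' @inheritParams equilibriumSpectrum
#' @return a list with one element per time point, each a
#'   `list(time = <h>, spectrum = <Spectrum>)`.
#' @export
autoxidationSeries <- function(kOx, duration, nSpectra = 25,
                               basis = defaultBasisSpectra(),
                               noise = NoiseModel(),
                               wavelengthGrid = seq(450, 650, by = 1)) {
  if (length(kOx) != 1 || !is.finite(kOx) || kOx <= 0)
    stop("kOx must be a single positive rate (h^-1)", call. = FALSE)
  if (length(duration) != 1 || !is.finite(duration) || duration <= 0)
    stop("duration must be positive (h)", call. = FALSE)
  if (nSpectra < 3) stop("need at least 3 spectra", call. = FALSE)
  tt <- seq(0, duration, length.out = nSpectra)
  oxyA <- basisAbsorbance(basis, "oxy", wavelengthGrid)
  ferA <- basisAbsorbance(basis, "ferric_hexa", wavelengthGrid)
  lapply(seq_along(tt), function(i) {
    f <- exp(-kOx * tt[i])
    a <- .addNoise(f * oxyA + (1 - f) * ferA, noise, stream = i - 1L)
    list(time = tt[i],
         spectrum = Spectrum(wavelengthGrid, a,
                             state = if (i == 1) "oxy" else "unknown",
                             sampleId = sprintf("autoox t=%.3g h", tt[i])))
  })
}
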