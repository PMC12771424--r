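#' @import methods
NULL

## Heme species tracked by the kinetic scheme, in canonical column order.
.hemeSpecies <- c("hexa", "penta", "oxy", "co")

## Heme states for which basis spectra are defined.
.basisStates <- c("penta_deoxy", "hexa_deoxy", "oxy", "carbonmonoxy",
                  "ferric_hexa", "ferric_penta")

.isFiniteNumeric <- function(x) is.numeric(x) && all(is.finite(x))

#' Visible absorbance spectrum of one hemoglobin sample
#'
#' A wavelength grid (nm, strictly increasing) with absorbances (AU) for a
#' single sample state. The `state` label records the heme oxidation/ligation
#' form the spectrum was collected in.
#'
#' @slot wavelength numeric, wavelengths in nm, strictly increasing.
#' @slot absorbance numeric, absorbances in AU, same length as `wavelength`.
#' @slot state character, one of `"ferric"`, `"ferrous-deoxy"`, `"oxy"`,
#'   `"carbonmonoxy"`, or `"unknown"`.
#' @slot sampleId character, free-form sample identifier.
#'
#' @examples
#' sp <- Spectrum(500:600, exp(-((500:600 - 555) / 20)^2), state = "ferrous-deoxy")
#' absorbanceAt(sp, 555)
#' @export
setClass("Spectrum",
  representation(wavelength = "numeric", absorbance = "numeric",
                 state = "character", sampleId = "character"),
  prototype(state = "unknown", sampleId = NA_character_))

setValidity("Spectrum", function(object) {
  msg <- NULL
  if (length(object@wavelength) != length(object@absorbance))
    msg <- c(msg, "wavelength and absorbance must have equal length")
  if (!.isFiniteNumeric(object@wavelength) || !.isFiniteNumeric(object@absorbance))
    msg <- c(msg, "wavelength and absorbance must be finite numeric")
  if (length(object@wavelength) > 1 && any(diff(object@wavelength) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  ok <- c("ferric", "ferrous-deoxy", "oxy", "carbonmonoxy", "unknown")
  if (length(object@state) != 1 || !object@state %in% ok)
    msg <- c(msg, paste("state must be one of:", paste(ok, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' @rdname Spectrum-class
#' @param wavelength,absorbance numeric vectors of equal length.
#' @param state sample state label.
#' @param sampleId sample identifier.
#' @export
Spectrum <- function(wavelength, absorbance, state = "unknown",
                     sampleId = NA_character_) {
  new("Spectrum", wavelength = as.numeric(wavelength),
      absorbance = as.numeric(absorbance), state = state, sampleId = sampleId)
}

#' Kinetic trace at a single monitor wavelength
#'
#' A time course of absorbance (OD) or absorbance change (delta-OD) at one
#' wavelength, with the ligand concentrations that applied during the
#' measurement. Times are stored in the unit named by `timeUnit`
#' (`"s"` or `"h"`); analysis functions convert as needed.
#'
#' @slot time numeric, strictly increasing, first value >= 0.
#' @slot signal numeric, same length as `time`.
#' @slot monitorWavelength numeric(1), nm.
#' @slot o2Conc,coConc numeric(1), ligand concentrations in uM (`NA` if absent).
#' @slot replicateId character(1), replicate identifier; `"averaged"` marks a
#'   pointwise mean of replicates.
#' @slot timeUnit character(1), `"s"` or `"h"`.
#' @slot meta list, free-form provenance (e.g. the true relaxation rate of a
#'   simulated trace under `$trueRate`).
#' @export
setClass("KineticTrace",
  representation(time = "numeric", signal = "numeric",
                 monitorWavelength = "numeric", o2Conc = "numeric",
                 coConc = "numeric", replicateId = "character",
                 timeUnit = "character", meta = "list"),
  prototype(monitorWavelength = NA_real_, o2Conc = NA_real_, coConc = NA_real_,
            replicateId = "1", timeUnit = "s", meta = list()))

setValidity("KineticTrace", function(object) {
  msg <- NULL
  if (length(object@time) != length(object@signal))
    msg <- c(msg, "time and signal must have equal length")
  if (length(object@time) < 3)
    msg <- c(msg, "a kinetic trace needs at least 3 points")
  if (!.isFiniteNumeric(object@time) || !.isFiniteNumeric(object@signal))
    msg <- c(msg, "time and signal must be finite numeric")
  else {
    if (object@time[1] < 0) msg <- c(msg, "first time point must be >= 0")
    if (any(diff(object@time) <= 0))
      msg <- c(msg, "time must be strictly increasing")
  }
  if (!object@timeUnit %in% c("s", "h"))
    msg <- c(msg, "timeUnit must be 's' or 'h'")
  if (is.null(msg)) TRUE else msg
})

#' @rdname KineticTrace-class
#' @param time,signal numeric vectors of equal length (>= 8 points).
#' @param monitorWavelength monitor wavelength in nm.
#' @param o2Conc,coConc ligand concentrations in uM.
#' @param replicateId replicate identifier.
#' @param timeUnit `"s"` (default) or `"h"`.
#' @param meta list of free-form metadata.
#' @export
KineticTrace <- function(time, signal, monitorWavelength = NA_real_,
                         o2Conc = NA_real_, coConc = NA_real_,
                         replicateId = "1", timeUnit = "s", meta = list()) {
  new("KineticTrace", time = as.numeric(time), signal = as.numeric(signal),
      monitorWavelength = as.numeric(monitorWavelength),
      o2Conc = as.numeric(o2Conc), coConc = as.numeric(coConc),
      replicateId = replicateId, timeUnit = timeUnit, meta = meta)
}

#' The hexacoordinate-globin kinetic scheme
#'
#' Six rate constants of the mass-action scheme
#' hexa-deoxy <-> penta-deoxy <-> ligand-bound:
#' the distal histidine binds the penta heme (`kHOn`, s^-1) and dissociates
#' (`kHOff`, s^-1); O2 and CO bind the penta heme bimolecularly
#' (`kPrimeO2`, `kPrimeCO`, uM^-1 s^-1) and dissociate (`kO2Off`, `kCOOff`,
#' s^-1). The hexacoordination equilibrium constant is
#' `K_H = kHOn / kHOff`.
#'
#' @slot kHOn,kHOff unimolecular distal-His binding/dissociation rates (s^-1).
#' @slot kPrimeO2,kPrimeCO bimolecular association rates to the
#'   pentacoordinate heme (uM^-1 s^-1).
#' @slot kO2Off,kCOOff ligand dissociation rates (s^-1).
#' @export
setClass("KineticScheme",
  representation(kHOn = "numeric", kHOff = "numeric",
                 kPrimeO2 = "numeric", kO2Off = "numeric",
                 kPrimeCO = "numeric", kCOOff = "numeric"))

setValidity("KineticScheme", function(object) {
  r <- c(object@kHOn, object@kHOff, object@kPrimeO2, object@kO2Off,
         object@kPrimeCO, object@kCOOff)
  if (length(r) != 6 || !.isFiniteNumeric(r))
    return("all six rates must be single finite numbers")
  if (any(r < 0)) return("rates must be >= 0")
  TRUE
})

#' @rdname KineticScheme-class
#' @param kHOn,kHOff,kPrimeO2,kO2Off,kPrimeCO,kCOOff rate constants, see slots.
#' @export
KineticScheme <- function(kHOn = 0, kHOff = 0, kPrimeO2 = 0, kO2Off = 0,
                          kPrimeCO = 0, kCOOff = 0) {
  new("KineticScheme", kHOn = as.numeric(kHOn), kHOff = as.numeric(kHOff),
      kPrimeO2 = as.numeric(kPrimeO2), kO2Off = as.numeric(kO2Off),
      kPrimeCO = as.numeric(kPrimeCO), kCOOff = as.numeric(kCOOff))
}

#' Time-resolved species composition of the heme pool
#'
#' Fractions of total heme in each of the four tracked species
#' (hexa-deoxy, penta-deoxy, O2-bound, CO-bound) over a time grid, as produced
#' by [simulateScheme()]. Fractions lie in `[0, 1]` and sum to 1 at every
#' time point (total heme is conserved).
#'
#' @slot time numeric, seconds, strictly increasing.
#' @slot fractions numeric matrix, one row per time point, columns
#'   `hexa`, `penta`, `oxy`, `co`.
#' @slot o2Conc,coConc numeric(1), the pseudo-first-order ligand
#'   concentrations (uM) used.
#' @export
setClass("SpeciesTrajectory",
  representation(time = "numeric", fractions = "matrix",
                 o2Conc = "numeric", coConc = "numeric"))

setValidity("SpeciesTrajectory", function(object) {
  msg <- NULL
  if (nrow(object@fractions) != length(object@time))
    msg <- c(msg, "fractions must have one row per time point")
  if (!identical(colnames(object@fractions), .hemeSpecies))
    msg <- c(msg, "fraction columns must be hexa, penta, oxy, co")
  f <- object@fractions
  if (any(!is.finite(f)) || any(f < -1e-9) || any(f > 1 + 1e-9))
    msg <- c(msg, "fractions must lie in [0, 1]")
  else if (any(abs(rowSums(f) - 1) > 1e-9))
    msg <- c(msg, "fractions must sum to 1 (mass conservation)")
  if (is.null(msg)) TRUE else msg
})

#' Gaussian basis spectra for the heme states
#'
#' For each heme state, a set of Gaussian absorbance bands
#' (center in nm, full width at half maximum in nm, peak amplitude in AU).
#' Mixture spectra and trace signals are rendered as fraction-weighted sums
#' of these bases. See [defaultBasisSpectra()] for the shipped defaults.
#'
#' @slot bands named list (one element per state in `penta_deoxy`,
#'   `hexa_deoxy`, `oxy`, `carbonmonoxy`, `ferric_hexa`, `ferric_penta`) of
#'   data.frames with columns `center`, `fwhm`, `amplitude`.
#' @export
setClass("BasisSpectra", representation(bands = "list"))

setValidity("BasisSpectra", function(object) {
  msg <- NULL
  if (!all(.basisStates %in% names(object@bands)))
    msg <- c(msg, paste("bands must include:", paste(.basisStates, collapse = ", ")))
  for (st in intersect(.basisStates, names(object@bands))) {
    b <- object@bands[[st]]
    if (!is.data.frame(b) || !all(c("center", "fwhm", "amplitude") %in% names(b))) {
      msg <- c(msg, sprintf("bands$%s needs columns center, fwhm, amplitude", st))
      next
    }
    if (any(!is.finite(as.matrix(b[c("center", "fwhm", "amplitude")]))))
      msg <- c(msg, sprintf("bands$%s must be finite", st))
    else {
      if (any(b$fwhm <= 0)) msg <- c(msg, sprintf("bands$%s widths must be > 0", st))
      if (any(b$amplitude <= 0)) msg <- c(msg, sprintf("bands$%s amplitudes must be > 0", st))
      if (any(b$center < 200 | b$center > 1000))
        msg <- c(msg, sprintf("bands$%s centers must lie in 200-1000 nm", st))
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Additive Gaussian noise model
#'
#' I.i.d. zero-mean Gaussian noise added per point to simulated spectra and
#' traces. Identical `sd` and `seed` reproduce identical output.
#'
#' @slot sd numeric(1), standard deviation (AU or delta-OD), >= 0.
#' @slot seed integer(1), RNG seed.
#' @export
setClass("NoiseModel", representation(sd = "numeric", seed = "integer"),
         prototype(sd = 0, seed = 1L))

setValidity("NoiseModel", function(object) {
  if (length(object@sd) != 1 || !is.finite(object@sd) || object@sd < 0)
    return("sd must be a single finite number >= 0")
  if (length(object@seed) != 1 || is.na(object@seed))
    return("seed must be a single integer")
  TRUE
})

#' @rdname NoiseModel-class
#' @param sd noise standard deviation (>= 0).
#' @param seed integer RNG seed.
#' @export
NoiseModel <- function(sd = 0, seed = 1L) {
  new("NoiseModel", sd = as.numeric(sd), seed = as.integer(seed))
}

#' Empirical calibration from A555/A540 ratio to fraction hexacoordinate
#'
#' Ordered anchor points mapping the ferrous-deoxy A555/A540 peak/trough
#' ratio to the fraction of hexacoordinate heme, interpolated monotonically
#' (piecewise linear). Must contain the two boundary anchors (a fully
#' pentacoordinate and a fully hexacoordinate reference). Ratios outside the
#' anchored range clamp to 0 or 1.
#'
#' @slot ratio numeric, strictly increasing anchor ratios.
#' @slot fh numeric, fractions hexacoordinate in `[0, 1]`, non-decreasing.
#' @seealso [defaultCalibration()], [calibrationFromBasis()]
#' @export
setClass("CalibrationTable", representation(ratio = "numeric", fh = "numeric"))

setValidity("CalibrationTable", function(object) {
  msg <- NULL
  if (length(object@ratio) != length(object@fh) || length(object@ratio) < 2)
    msg <- c(msg, "need >= 2 anchor points with matching lengths")
  if (!.isFiniteNumeric(object@ratio) || !.isFiniteNumeric(object@fh))
    msg <- c(msg, "anchors must be finite numeric")
  else {
    if (any(diff(object@ratio) <= 0)) msg <- c(msg, "ratios must be strictly increasing")
    if (any(object@fh < 0 | object@fh > 1)) msg <- c(msg, "F_H anchors must lie in [0, 1]")
    if (any(diff(object@fh) < 0)) msg <- c(msg, "F_H anchors must be non-decreasing")
    if (!any(object@fh == 0) || !any(object@fh == 1))
      msg <- c(msg, "calibration must contain the F_H = 0 and F_H = 1 boundary anchors")
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname CalibrationTable-class
#' @param ratio,fh anchor vectors (see slots).
#' @export
CalibrationTable <- function(ratio, fh) {
  new("CalibrationTable", ratio = as.numeric(ratio), fh = as.numeric(fh))
}

#' Ferrous heme coordination estimate
#'
#' The (ratio, F_H, K_H) triple for one protein: the A555/A540 peak/trough
#' ratio, the fraction hexacoordinate derived from it, and the
#' hexacoordination equilibrium constant `K_H = F_H / (1 - F_H)`.
#' `kH` is `Inf` (with `kHCapped = TRUE`) for effectively fully
#' hexacoordinate samples.
#'
#' @slot ratio numeric(1), A555/A540.
#' @slot fh numeric(1), fraction hexacoordinate in `[0, 1]`.
#' @slot kH numeric(1), equilibrium constant (>= 0, possibly `Inf`).
#' @slot kHCapped logical(1), `TRUE` when F_H was at/above the reporting cap.
#' @export
setClass("CoordinationResult",
  representation(ratio = "numeric", fh = "numeric", kH = "numeric",
                 kHCapped = "logical"),
  prototype(kHCapped = FALSE))

setValidity("CoordinationResult", function(object) {
  msg <- NULL
  if (!is.finite(object@fh) || object@fh < 0 || object@fh > 1)
    msg <- c(msg, "fh must lie in [0, 1]")
  if (is.finite(object@kH)) {
    if (object@kH < 0) msg <- c(msg, "kH must be >= 0")
    else if (abs(object@fh - object@kH / (1 + object@kH)) > 1e-12)
      msg <- c(msg, "fh and kH must satisfy fh = kH / (1 + kH)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Single-exponential fit of a kinetic trace
#'
#' Model: `y(t) = offset + amplitude * exp(-kObs * t)`. `degenerate` marks a
#' flat trace (amplitude indistinguishable from zero); `accepted` is `FALSE`
#' when the fit did not converge, `kObs <= 0`, or R^2 < 0.9.
#'
#' @slot amplitude,offset signal units.
#' @slot kObs relaxation rate (per unit of the fitted trace's time axis).
#' @slot seKObs standard error of `kObs`.
#' @slot rss residual sum of squares.
#' @slot r2 coefficient of determination.
#' @slot converged,degenerate,accepted logical fit status flags.
#' @export
setClass("ExponentialFit",
  representation(amplitude = "numeric", kObs = "numeric", offset = "numeric",
                 rss = "numeric", seKObs = "numeric", r2 = "numeric",
                 converged = "logical", degenerate = "logical",
                 accepted = "logical"))

#' Oxygen binding constants of one hemoglobin
#'
#' Rate and equilibrium constants for O2 binding: bimolecular association to
#' the pentacoordinate intermediate (`kPrimeO2Pent`), the corrected O2
#' dissociation rate (`kO2`), the pentacoordinate association equilibrium
#' constant `K_O2,pent = k'_O2,pent / k_O2` (uM^-1) and the
#' hexacoordination-corrected affinity `K_O2 = K_O2,pent / (1 + K_H)`.
#'
#' @slot kPrimeO2Pent uM^-1 s^-1.
#' @slot kO2 s^-1.
#' @slot kPrimeCOPent uM^-1 s^-1 (may be `NA`).
#' @slot kO2Pent,kO2Eq uM^-1 (`kO2Eq` is K_O2).
#' @slot kH the hexacoordination constant used.
#' @slot kO2PentSource `"rates"` or `"override"`.
#' @export
setClass("BindingConstants",
  representation(kPrimeO2Pent = "numeric", kO2 = "numeric",
                 kPrimeCOPent = "numeric", kO2Pent = "numeric",
                 kO2Eq = "numeric", kH = "numeric", kO2PentSource = "character"))

setValidity("BindingConstants", function(object) {
  msg <- NULL
  if (object@kO2PentSource == "rates" && is.finite(object@kO2) && object@kO2 > 0 &&
      abs(object@kO2Pent - object@kPrimeO2Pent / object@kO2) > 1e-9 * max(1, object@kO2Pent))
    msg <- c(msg, "kO2Pent must equal kPrimeO2Pent / kO2 when computed from rates")
  if (is.finite(object@kH)) {
    if (abs(object@kO2Eq - object@kO2Pent / (1 + object@kH)) >
        1e-12 * max(1, object@kO2Pent))
      msg <- c(msg, "kO2Eq must equal kO2Pent / (1 + kH)")
  } else if (object@kO2Eq != 0) {
    msg <- c(msg, "kO2Eq must be 0 when kH is infinite")
  }
  if (is.null(msg)) TRUE else msg
})

#' Autoxidation rate of the oxy complex
#'
#' The single-exponential autoxidation rate constant `kOx` (h^-1) of the
#' ferrous-oxy to ferric transition, with the corresponding half-life
#' `tHalf = 60 * ln(2) / kOx` (min) and fit diagnostics.
#'
#' @slot kOx h^-1, > 0.
#' @slot tHalf min.
#' @slot seKOx standard error of `kOx` (h^-1).
#' @slot rss residual sum of squares of the underlying fit.
#' @export
setClass("AutooxResult",
  representation(kOx = "numeric", tHalf = "numeric", seKOx = "numeric",
                 rss = "numeric"))

setValidity("AutooxResult", function(object) {
  if (!is.finite(object@kOx) || object@kOx <= 0)
    return("kOx must be a positive finite rate")
  if (abs(object@kOx * object@tHalf - 60 * log(2)) > 1e-9)
    return("tHalf must equal 60 * ln(2) / kOx")
  TRUE
})

#' Per-protein analysis report
#'
#' Bundles the coordination, O2-binding and autoxidation results of one
#' protein together with provenance (inputs, seeds, package version). Any
#' stage may be absent (`NULL`) if its inputs were missing or its fit failed;
#' failures are recorded in `errors`.
#'
#' @slot protein character(1) protein identifier.
#' @slot coordination a [CoordinationResult-class] or `NULL`.
#' @slot binding a [BindingConstants-class] or `NULL`.
#' @slot autoox an [AutooxResult-class] or `NULL`.
#' @slot provenance list (seeds, inputs, package version, fit diagnostics).
#' @slot errors character vector of per-stage error messages.
#' @export
setClass("ProteinReport",
  representation(protein = "character", coordination = "ANY", binding = "ANY",
                 autoox = "ANY", provenance = "list", errors = "character"),
  prototype(coordination = NULL, binding = NULL, autoox = NULL,
            provenance = list(), errors = character()))
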