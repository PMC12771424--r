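#' Interpolated absorbance of a spectrum at arbitrary wavelengths
#'
#' Linear interpolation between the bracketing grid points; exact grid hits
#' return the stored value. Queries outside the spectrum's span are an error.
#'
#' @param spectrum a [Spectrum-class].
#' @param wavelength numeric vector of query wavelengths (nm).
#' @return numeric vector of absorbances (AU).
#' @export
absorbanceAt <- function(spectrum, wavelength) {
  stopifnot(is(spectrum, "Spectrum"))
  wl <- spectrum@wavelength
  if (any(!is.finite(wavelength)) ||
      any(wavelength < wl[1]) || any(wavelength > wl[length(wl)]))
    stop(sprintf("query wavelength outside the spectrum span (%g-%g nm)",
                 wl[1], wl[length(wl)]), call. = FALSE)
  stats::approx(wl, spectrum@absorbance, xout = wavelength,
                method = "linear", ties = "ordered")$y
}

#' A555/A540 peak-to-trough ratio of a ferrous-deoxy spectrum
#'
#' The ratio of the absorbance peak at 555 nm to the absorbance trough at
#' 540 nm, the empirical reporter of ferrous heme hexacoordination: the
#' pentacoordinate deoxy heme has a single broad band near 555 nm, while the
#' hexacoordinate (bis-histidyl) heme splits into bands near 530 and 560 nm
#' with a trough between them.
#'
#' @param spectrum a [Spectrum-class] spanning 540 and 555 nm.
#' @param peak,trough query wavelengths in nm (fixed 555/540 by default;
#'   interpolated, not extremum-searched, for robustness to noisy shoulders).
#' @return the dimensionless ratio.
#' @export
peakTroughRatio <- function(spectrum, peak = 555, trough = 540) {
  a <- absorbanceAt(spectrum, c(peak, trough))
  if (a[2] <= 0)
    stop("absorbance at the trough wavelength is not positive; ratio undefined",
         call. = FALSE)
  a[1] / a[2]
}

#' Default A555/A540 -> F_H calibration
#'
#' Monotone piecewise-linear calibration anchored by a fully pentacoordinate
#' oxygen-transport reference (leghemoglobin a, ratio 1.2, F_H 0) and a fully
#' hexacoordinate reference (neuroglobin, ratio 3.1, F_H 1). Optionally adds
#' the partially hexacoordinate maize Hb1 interior anchor (ratio 1.8,
#' F_H 0.48); the published anchor points are not collinear, so the shape of
#' the interior of this empirical curve is genuinely uncertain — the
#' calibration is therefore a first-class, swappable input.
#'
#' @param includeMaize add the interior anchor (default `FALSE`).
#' @return a [CalibrationTable-class].
#' @export
defaultCalibration <- function(includeMaize = FALSE) {
  if (includeMaize) CalibrationTable(c(1.2, 1.8, 3.1), c(0, 0.48, 1))
  else CalibrationTable(c(1.2, 3.1), c(0, 1))
}

#' Build a ratio -> F_H calibration from basis spectra
#'
#' Computes the A555/A540 ratio of noiseless two-component mixture spectra at
#' a dense grid of hexacoordinate fractions and returns the resulting anchor
#' table. Using this calibration, coordination estimates on spectra rendered
#' from the same basis recover the generating F_H up to interpolation error.
#'
#' @param basis a [BasisSpectra-class].
#' @param n number of anchor points (>= 11).
#' @inheritParams peakTroughRatio
#' @return a [CalibrationTable-class].
#' @export
calibrationFromBasis <- function(basis = defaultBasisSpectra(), n = 201,
                                 peak = 555, trough = 540) {
  stopifnot(n >= 11)
  fh <- seq(0, 1, length.out = n)
  ratio <- vapply(fh, function(f) {
    num <- f * basisAbsorbance(basis, "hexa_deoxy", peak) +
      (1 - f) * basisAbsorbance(basis, "penta_deoxy", peak)
    den <- f * basisAbsorbance(basis, "hexa_deoxy", trough) +
      (1 - f) * basisAbsorbance(basis, "penta_deoxy", trough)
    num / den
  }, numeric(1))
  if (any(diff(ratio) < 0)) {    # orient so ratios increase with the table
    ord <- order(ratio)
    ratio <- ratio[ord]; fh <- fh[ord]
  }
  CalibrationTable(ratio, fh)
}

#' Convert an A555/A540 ratio to the fraction hexacoordinate
#'
#' Monotone piecewise-linear interpolation through the calibration anchors;
#' ratios below/above the boundary anchors clamp to F_H 0/1.
#'
#' @param ratio numeric vector of A555/A540 ratios.
#' @param calibration a [CalibrationTable-class].
#' @return F_H values in `[0, 1]`.
#' @export
ratioToFractionHexa <- function(ratio, calibration = defaultCalibration()) {
  stopifnot(is(calibration, "CalibrationTable"))
  validObject(calibration)
  out <- stats::approx(calibration@ratio, calibration@fh, xout = ratio,
                       method = "linear", rule = 2, ties = "ordered")$y
  pmin(pmax(out, 0), 1)
}

#' Hexacoordination equilibrium constant from the fraction hexacoordinate
#'
#' Inverts the coordination equilibrium relation `F_H = K_H / (1 + K_H)`:
#' `K_H = F_H / (1 - F_H)`. `F_H = 1` returns `Inf`.
#'
#' @param fh fraction(s) hexacoordinate in `[0, 1]`.
#' @return K_H value(s) in `[0, Inf]`.
#' @examples
#' fractionToKH(0.53)  # ~1.1
#' @export
fractionToKH <- function(fh) {
  if (any(!is.finite(fh)) || any(fh < 0) || any(fh > 1))
    stop("fh must lie in [0, 1]", call. = FALSE)
  ifelse(fh == 1, Inf, fh / (1 - fh))
}

#' Fraction hexacoordinate from the equilibrium constant
#'
#' `F_H = K_H / (1 + K_H)`, the forward form of the coordination
#' equilibrium relation.
#'
#' @param kH equilibrium constant(s), >= 0 (`Inf` allowed, mapping to 1).
#' @return F_H value(s) in `[0, 1]`.
#' @export
kHToFraction <- function(kH) {
  if (any(is.na(kH)) || any(kH < 0))
    stop("kH must be >= 0", call. = FALSE)
  ifelse(is.infinite(kH), 1, kH / (1 + kH))
}

#' Coordination-state estimate from a ferrous-deoxy spectrum
#'
#' Runs the full spectral pipeline: A555/A540 ratio, calibration lookup to
#' F_H, and inversion to K_H. F_H at or above `fhCap` reports `K_H = Inf`
#' with a warning (fully hexacoordinate references have K_H too large to
#' resolve spectrally; published values are order-of-magnitude only).
#'
#' @inheritParams peakTroughRatio
#' @inheritParams ratioToFractionHexa
#' @param fhCap F_H value at which K_H is reported as infinite (default
#'   0.999).
#' @return a [CoordinationResult-class].
#' @examples
#' sp <- equilibriumSpectrum(0.83)
#' coordinationFromSpectrum(sp, calibrationFromBasis())
#' @export
coordinationFromSpectrum <- function(spectrum,
                                     calibration = defaultCalibration(),
                                     peak = 555, trough = 540,
                                     fhCap = 0.999) {
  ratio <- peakTroughRatio(spectrum, peak = peak, trough = trough)
  fh <- ratioToFractionHexa(ratio, calibration)
  if (fh >= fhCap) {
    warning(sprintf(
      "F_H = %.4g is at/above the reporting cap (%g); K_H reported as Inf",
      fh, fhCap), call. = FALSE)
    new("CoordinationResult", ratio = ratio, fh = 1, kH = Inf, kHCapped = TRUE)
  } else {
    new("CoordinationResult", ratio = ratio, fh = fh, kH = fractionToKH(fh),
        kHCapped = FALSE)
  }
}
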