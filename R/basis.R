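#' Default Gaussian basis spectra for the heme states
#'
#' Band positions follow the qualitative visible-band features of plant and
#' animal globins: a single broad band near 555 nm for the pentacoordinate
#' ferrous-deoxy heme; split bands near 530 and 560 nm for the
#' hexacoordinate ferrous-deoxy (bis-histidyl) heme; the oxy alpha/beta pair
#' near 541/576 nm; carbonmonoxy bands near 540/569 nm; a 530 nm band with a
#' 560 nm shoulder for the hexacoordinate ferric state; and a broad
#' charge-transfer region with a 620 nm band for the pentacoordinate
#' (aquomet) ferric state. Each state also carries its Soret band
#' (403-431 nm) so that traces monitored in the Soret region have signal.
#' Widths (FWHM) and amplitudes are representative shapes, not fits; users
#' may supply their own [BasisSpectra-class].
#'
#' @return a [BasisSpectra-class] object.
#' @examples
#' b <- defaultBasisSpectra()
#' basisAbsorbance(b, "oxy", c(412, 541, 576))
#' @export
defaultBasisSpectra <- function() {
  band <- function(center, fwhm, amplitude)
    data.frame(center = center, fwhm = fwhm, amplitude = amplitude)
  new("BasisSpectra", bands = list(
    penta_deoxy  = band(c(431, 555),      c(30, 45),     c(2.2, 0.50)),
    hexa_deoxy   = band(c(425, 530, 560), c(24, 17, 16), c(2.6, 0.35, 0.50)),
    oxy          = band(c(412, 541, 576), c(22, 18, 18), c(2.4, 0.30, 0.33)),
    carbonmonoxy = band(c(420, 540, 569), c(20, 18, 18), c(2.8, 0.30, 0.30)),
    ferric_hexa  = band(c(409, 530, 560), c(26, 20, 20), c(2.3, 0.25, 0.12)),
    ferric_penta = band(c(403, 500, 620), c(30, 50, 25), c(2.2, 0.20, 0.12))
  ))
}

#' Evaluate a basis spectrum at given wavelengths
#'
#' Sums the Gaussian bands of one heme state:
#' `A(lambda) = sum_i a_i * exp(-4 ln2 ((lambda - c_i) / w_i)^2)`.
#'
#' @param basis a [BasisSpectra-class].
#' @param state one of `"penta_deoxy"`, `"hexa_deoxy"`, `"oxy"`,
#'   `"carbonmonoxy"`, `"ferric_hexa"`, `"ferric_penta"`.
#' @param wavelength numeric vector of wavelengths (nm).
#' @return numeric vector of absorbances (AU).
#' @export
basisAbsorbance <- function(basis, state, wavelength) {
  stopifnot(is(basis, "BasisSpectra"))
  state <- match.arg(state, .basisStates)
  b <- basis@bands[[state]]
  out <- numeric(length(wavelength))
  for (i in seq_len(nrow(b)))
    out <- out + b$amplitude[i] *
      exp(-4 * log(2) * ((wavelength - b$center[i]) / b$fwhm[i])^2)
  out
}

## Absorbance of each kinetic species at one wavelength, in scheme species
## order (hexa, penta, oxy, co). Ferrous-deoxy states only: photokinetics are
## measured on ferrous samples.
.speciesAbsorbance <- function(basis, wavelength) {
  c(hexa  = basisAbsorbance(basis, "hexa_deoxy", wavelength),
    penta = basisAbsorbance(basis, "penta_deoxy", wavelength),
    oxy   = basisAbsorbance(basis, "oxy", wavelength),
    co    = basisAbsorbance(basis, "carbonmonoxy", wavelength))
}

## Default rendered wavelength span (nm); monitor wavelengths must fall inside.
.defaultWavelengthRange <- c(350, 700)

.checkMonitorWavelength <- function(wavelength, range = .defaultWavelengthRange) {
  if (length(wavelength) != 1 || !is.finite(wavelength) ||
      wavelength < range[1] || wavelength > range[2])
    stop(sprintf("monitor wavelength must lie within the rendered %g-%g nm span",
                 range[1], range[2]), call. = FALSE)
  invisible(wavelength)
}

## Seeded i.i.d. Gaussian noise; leaves the caller's RNG state untouched.
.addNoise <- function(x, noise, stream = 0L) {
  stopifnot(is(noise, "NoiseModel"))
  if (noise@sd == 0) return(x)
  withr::with_seed(noise@seed + stream, x + stats::rnorm(length(x), 0, noise@sd))
}
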