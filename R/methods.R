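#' @rdname Spectrum-class
#' @export
setMethod("wavelengths", "Spectrum", function(x) x@wavelength)

#' @rdname Spectrum-class
#' @export
setMethod("absorbances", "Spectrum", function(x) x@absorbance)

#' @rdname Spectrum-class
#' @export
setMethod("length", "Spectrum", function(x) length(x@wavelength))

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum (%s): %d points, %.0f-%.0f nm",
              object@state, length(object@wavelength),
              min(object@wavelength), max(object@wavelength)))
  if (!is.na(object@sampleId)) cat(sprintf(" [%s]", object@sampleId))
  cat("\n")
})

#' @rdname KineticTrace-class
#' @export
setMethod("times", "KineticTrace", function(x) x@time)

#' @rdname KineticTrace-class
#' @export
setMethod("signals", "KineticTrace", function(x) x@signal)

#' @rdname KineticTrace-class
#' @export
setMethod("length", "KineticTrace", function(x) length(x@time))

setMethod("show", "KineticTrace", function(object) {
  cat(sprintf("KineticTrace: %d points, %g-%g %s", length(object@time),
              object@time[1], object@time[length(object@time)],
              object@timeUnit))
  if (!is.na(object@monitorWavelength))
    cat(sprintf(", monitored at %g nm", object@monitorWavelength))
  cat("\n")
  concs <- c(if (!is.na(object@o2Conc)) sprintf("[O2] = %g uM", object@o2Conc),
             if (!is.na(object@coConc)) sprintf("[CO] = %g uM", object@coConc))
  if (length(concs)) cat(" ", paste(concs, collapse = ", "), "\n")
})

#' @rdname hexaKH
#' @export
setMethod("hexaKH", "KineticScheme", function(x) x@kHOn / x@kHOff)

#' @rdname hexaKH
#' @export
setMethod("hexaKH", "CoordinationResult", function(x) x@kH)

setMethod("show", "KineticScheme", function(object) {
  cat("KineticScheme (hexa <-> penta <-> ligand-bound)\n")
  cat(sprintf("  His:  on %g s^-1, off %g s^-1 (K_H = %g)\n",
              object@kHOn, object@kHOff, hexaKH(object)))
  cat(sprintf("  O2:   k' %g uM^-1 s^-1, off %g s^-1\n",
              object@kPrimeO2, object@kO2Off))
  cat(sprintf("  CO:   k' %g uM^-1 s^-1, off %g s^-1\n",
              object@kPrimeCO, object@kCOOff))
})

#' @rdname SpeciesTrajectory-class
#' @export
setMethod("speciesFractions", "SpeciesTrajectory", function(x) x@fractions)

#' @rdname SpeciesTrajectory-class
#' @export
setMethod("times", "SpeciesTrajectory", function(x) x@time)

setMethod("show", "SpeciesTrajectory", function(object) {
  cat(sprintf("SpeciesTrajectory: %d time points over %g s\n",
              length(object@time), max(object@time)))
  f <- object@fractions[nrow(object@fractions), ]
  cat("  final fractions:",
      paste(sprintf("%s %.3f", colnames(object@fractions), f), collapse = ", "),
      "\n")
})

setMethod("show", "CoordinationResult", function(object) {
  kh <- if (object@kHCapped) ">= cap" else format(object@kH, digits = 3)
  cat(sprintf("CoordinationResult: A555/A540 = %.3g, F_H = %.3g, K_H = %s\n",
              object@ratio, object@fh, kh))
})

setMethod("show", "ExponentialFit", function(object) {
  if (object@degenerate) {
    cat("ExponentialFit: degenerate (flat trace, amplitude 0)\n")
  } else {
    cat(sprintf(
      "ExponentialFit: k_obs = %.6g +/- %.2g, amplitude %.4g, offset %.4g\n",
      object@kObs, object@seKObs, object@amplitude, object@offset))
    cat(sprintf("  R^2 = %.5f, %s\n", object@r2,
                if (object@accepted) "accepted" else "FLAGGED"))
  }
})

setMethod("show", "BindingConstants", function(object) {
  cat("BindingConstants:\n")
  cat(sprintf("  k'_O2,pent = %.4g uM^-1 s^-1, k_O2 = %.4g s^-1\n",
              object@kPrimeO2Pent, object@kO2))
  cat(sprintf("  K_O2,pent = %.4g uM^-1 (%s), K_O2 = %.4g uM^-1 (K_H = %.4g)\n",
              object@kO2Pent, object@kO2PentSource, object@kO2Eq, object@kH))
})

setMethod("show", "AutooxResult", function(object) {
  cat(sprintf("AutooxResult: k_ox = %.4g h^-1 (t_1/2 = %.3g min)\n",
              object@kOx, object@tHalf))
})

setMethod("show", "ProteinReport", function(object) {
  cat(sprintf("ProteinReport for %s\n", object@protein))
  for (sl in c("coordination", "binding", "autoox")) {
    v <- slot(object, sl)
    if (is.null(v)) cat(sprintf("  %s: <absent>\n", sl)) else show(v)
  }
  if (length(object@errors))
    cat("  errors:", paste(object@errors, collapse = "; "), "\n")
})
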