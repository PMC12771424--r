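#' @rdname Spectrum-class
#' @param x an object.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname Spectrum-class
#' @export
setGeneric("absorbances", function(x) standardGeneric("absorbances"))

#' @rdname KineticTrace-class
#' @param x an object.
#' @export
setGeneric("times", function(x) standardGeneric("times"))

#' @rdname KineticTrace-class
#' @export
setGeneric("signals", function(x) standardGeneric("signals"))

#' Hexacoordination equilibrium constant of a scheme or result
#'
#' For a [KineticScheme-class], `K_H = kHOn / kHOff`; for a
#' [CoordinationResult-class], the spectrally estimated constant.
#'
#' @param x the object.
#' @return a single number (possibly `Inf`; `NaN` for a 0/0 scheme).
#' @export
setGeneric("hexaKH", function(x) standardGeneric("hexaKH"))

#' @rdname SpeciesTrajectory-class
#' @param x a trajectory.
#' @export
setGeneric("speciesFractions", function(x) standardGeneric("speciesFractions"))
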