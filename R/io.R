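#' Read and write spectrum files
#'
#' Spectra travel as two-column delimited text with header
#' `wavelength_nm,absorbance`; the state label and sample id ride in
#' `# key: value` comment lines above the header.
#'
#' @param file path to a spectrum file.
#' @return `readSpectrum` returns a [Spectrum-class].
#' @export
readSpectrum <- function(file) {
  meta <- .readHashMeta(file)
  d <- utils::read.csv(file, comment.char = "#")
  if (!all(c("wavelength_nm", "absorbance") %in% names(d)))
    stop("spectrum file needs columns wavelength_nm, absorbance", call. = FALSE)
  Spectrum(d$wavelength_nm, d$absorbance,
           state = meta[["state"]] %||% "unknown",
           sampleId = meta[["sample_id"]] %||% NA_character_)
}

#' @rdname readSpectrum
#' @param spectrum a [Spectrum-class].
#' @export
writeSpectrum <- function(spectrum, file) {
  stopifnot(is(spectrum, "Spectrum"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# state: %s", spectrum@state), con)
  if (!is.na(spectrum@sampleId))
    writeLines(sprintf("# sample_id: %s", spectrum@sampleId), con)
  writeLines("wavelength_nm,absorbance", con)
  writeLines(sprintf("%.12g,%.12g", spectrum@wavelength, spectrum@absorbance),
             con)
  invisible(file)
}

#' Read and write kinetic trace files
#'
#' Traces travel as two-column delimited text with header `time_s,signal`
#' (or `time_h,signal` for hour-based series); monitor wavelength, ligand
#' concentrations and replicate id ride in `# key: value` comment lines.
#'
#' @param file path to a trace file.
#' @return `readTrace` returns a [KineticTrace-class].
#' @export
readTrace <- function(file) {
  meta <- .readHashMeta(file)
  d <- utils::read.csv(file, comment.char = "#")
  tcol <- intersect(c("time_s", "time_h"), names(d))
  if (length(tcol) != 1 || !"signal" %in% names(d))
    stop("trace file needs columns time_s (or time_h) and signal", call. = FALSE)
  num <- function(key) if (is.null(meta[[key]])) NA_real_ else as.numeric(meta[[key]])
  KineticTrace(d[[tcol]], d$signal,
               monitorWavelength = num("monitor_wavelength_nm"),
               o2Conc = num("o2_uM"), coConc = num("co_uM"),
               replicateId = meta[["replicate_id"]] %||% "1",
               timeUnit = if (tcol == "time_h") "h" else "s")
}

#' @rdname readTrace
#' @param trace a [KineticTrace-class].
#' @export
writeTrace <- function(trace, file) {
  stopifnot(is(trace, "KineticTrace"))
  con <- file(file, "w")
  on.exit(close(con))
  putNum <- function(key, v) if (!is.na(v)) writeLines(sprintf("# %s: %.12g", key, v), con)
  putNum("monitor_wavelength_nm", trace@monitorWavelength)
  putNum("o2_uM", trace@o2Conc)
  putNum("co_uM", trace@coConc)
  writeLines(sprintf("# replicate_id: %s", trace@replicateId), con)
  writeLines(sprintf("time_%s,signal", trace@timeUnit), con)
  writeLines(sprintf("%.12g,%.12g", trace@time, trace@signal), con)
  invisible(file)
}

#' Read a calibration table file
#'
#' Delimited text with header `ratio,fraction_hexa`.
#'
#' @param file path.
#' @return a [CalibrationTable-class].
#' @export
readCalibration <- function(file) {
  d <- utils::read.csv(file, comment.char = "#")
  if (!all(c("ratio", "fraction_hexa") %in% names(d)))
    stop("calibration file needs columns ratio, fraction_hexa", call. = FALSE)
  CalibrationTable(d$ratio, d$fraction_hexa)
}

#' Read a pipeline run configuration
#'
#' YAML key-value configuration with explicit units in key names; see the
#' shipped example (`system.file("extdata", "example-config.yaml",
#' package = "HbKinetics")`) and [runPipeline()] for the schema.
#'
#' @param file path to a YAML config.
#' @return a named list.
#' @export
readRunConfig <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file, call. = FALSE)
  yaml::read_yaml(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## "# key: value" comment headers
.readHashMeta <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file, call. = FALSE)
  lines <- readLines(file, n = 50)
  lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  meta
}
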