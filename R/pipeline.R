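#' Run the full spectro-kinetic analysis pipeline
#'
#' Orchestrates, per protein: coordination-state estimation from the
#' ferrous-deoxy spectrum; single-exponential fitting of flash-photolysis
#' (O2 and CO) and stopped-flow displacement traces; bimolecular rate
#' regression; the CO-competition correction of the O2 dissociation rate;
#' assembly of the O2 binding constants; and the autoxidation fit. Each
#' protein's inputs come either from files or from simulation ground truth
#' (exactly one of the two), and per-protein failures are recorded in the
#' report rather than aborting the run.
#'
#' The configuration is a named list (typically from [readRunConfig()]):
#' \describe{
#'   \item{seed}{integer, master seed for all simulated noise (default 1).}
#'   \item{o2_air_uM}{O2 concentration of air-equilibrated buffer used for
#'     flash photolysis (default 262).}
#'   \item{calibration}{`"default"`, `"default+maize"`, `"basis"` (built
#'     from the active basis spectra; the right choice for simulated runs),
#'     or a file path.}
#'   \item{proteins}{named list; each element has either `simulate` (keys
#'     `F_H`, `k_prime_O2_uM_s`, `k_O2_off_s`, `k_prime_CO_uM_s`,
#'     optional `k_CO_off_s`, `k_ox_per_h`, `noise_sd`, `n_replicates`,
#'     `stopped_flow: {o2_uM, co_uM}`, `co_concs_uM`) or `inputs` (keys
#'     `spectrum`, `flash_o2_traces`, `flash_co_traces`,
#'     `stopped_flow_trace`, `autoox_manifest`, optional `k_H`).}
#'   \item{output_dir}{optional; when set, reports and the run log are
#'     written there via [writeReport()].}
#' }
#'
#' Simulated kinetics use a scheme with distal-His rebinding disabled: the
#' photolyzed/displacement intermediate is treated as purely
#' pentacoordinate, matching the kinetic model under which the association
#' rates and the competition correction are defined; hexacoordination
#' enters through the equilibrium spectrum (K_H) alone.
#'
#' @param config a named list as above, or a path to a YAML file.
#' @return a list of [ProteinReport-class] objects (one per configured
#'   protein, in configuration order).
#' @seealso [writeReport()], [readRunConfig()]
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1) config <- readRunConfig(config)
  if (!is.list(config)) stop("config must be a list or a YAML path", call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  o2Air <- as.numeric(config$o2_air_uM %||% 262)
  basis <- defaultBasisSpectra()
  cal <- .resolveCalibration(config$calibration %||% "default", basis)
  proteins <- config$proteins %||% list()
  if (length(proteins) && is.null(names(proteins)))
    stop("config$proteins must be a named list", call. = FALSE)

  reports <- vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    nm <- names(proteins)[i]
    pc <- proteins[[i]]
    if (is.null(pc$simulate) == is.null(pc$inputs))
      stop(sprintf("protein '%s': exactly one of simulate/inputs required", nm),
           call. = FALSE)
    reports[[i]] <- .analyzeProtein(nm, pc, cal = cal, basis = basis,
                                    o2Air = o2Air,
                                    seed = seed + 1000L * (i - 1L))
  }
  if (!is.null(config$output_dir))
    writeReport(reports, config$output_dir,
                format = config$report_format %||% "delimited")
  reports
}

.resolveCalibration <- function(spec, basis) {
  if (is(spec, "CalibrationTable")) return(spec)
  if (identical(spec, "default")) return(defaultCalibration())
  if (identical(spec, "default+maize")) return(defaultCalibration(includeMaize = TRUE))
  if (identical(spec, "basis")) return(calibrationFromBasis(basis))
  if (is.character(spec) && file.exists(spec)) return(readCalibration(spec))
  stop("unrecognized calibration specification", call. = FALSE)
}

## One protein end to end; every stage trapped so that a failure surfaces in
## the report's errors field rather than aborting the whole run.
.analyzeProtein <- function(name, pc, cal, basis, o2Air, seed) {
  errors <- character()
  fits <- list()
  note <- function(stage, e) {
    errors <<- c(errors, sprintf("%s: %s", stage, conditionMessage(e)))
    NULL
  }
  inp <- tryCatch({
    if (is.null(pc$simulate)) .loadInputs(pc$inputs)
    else .simulateInputs(pc$simulate, basis, o2Air, seed)
  }, error = function(e) note("inputs", e))
  if (is.null(inp))
    return(new("ProteinReport", protein = name,
               provenance = list(seed = seed), errors = errors))

  coordination <- tryCatch({
    if (is.null(inp$spectrum)) NULL
    else coordinationFromSpectrum(inp$spectrum, cal)
  }, error = function(e) note("coordination", e))

  binding <- tryCatch({
    kH <- if (!is.null(inp$kHOverride)) inp$kHOverride
          else if (!is.null(coordination)) coordination@kH
          else stop("no K_H available (no spectrum and no k_H override)")
    .deriveBinding(inp, kH, o2Air, fits = function(f) fits <<- c(fits, f))
  }, error = function(e) note("binding", e))

  autoox <- tryCatch({
    if (is.null(inp$autooxSeries)) NULL
    else fitAutoox(extractTimecourse(inp$autooxSeries))
  }, error = function(e) note("autoox", e))

  new("ProteinReport", protein = name, coordination = coordination,
      binding = binding, autoox = autoox,
      provenance = list(seed = seed, mode = inp$mode,
                        version = as.character(utils::packageVersion("HbKinetics")),
                        fits = fits),
      errors = errors)
}

## ---- input assembly -------------------------------------------------------

.loadInputs <- function(paths) {
  rd <- function(p, f) if (is.null(p)) NULL else f(p)
  autoox <- NULL
  if (!is.null(paths$autoox_manifest)) {
    man <- utils::read.csv(paths$autoox_manifest, comment.char = "#")
    if (!all(c("time_h", "file") %in% names(man)))
      stop("autoox manifest needs columns time_h, file", call. = FALSE)
    base <- dirname(paths$autoox_manifest)
    autoox <- lapply(seq_len(nrow(man)), function(i)
      list(time = man$time_h[i],
           spectrum = readSpectrum(file.path(base, man$file[i]))))
  }
  list(mode = "files",
       spectrum = rd(paths$spectrum, readSpectrum),
       flashO2 = lapply(paths$flash_o2_traces %||% list(), readTrace),
       flashCO = lapply(paths$flash_co_traces %||% list(), readTrace),
       stoppedFlow = rd(paths$stopped_flow_trace, readTrace),
       autooxSeries = autoox,
       kHOverride = if (is.null(paths$k_H)) NULL else as.numeric(paths$k_H))
}

.simulateInputs <- function(truth, basis, o2Air, seed) {
  num <- function(key, default = NULL) {
    v <- truth[[key]] %||% default
    if (is.null(v)) stop("simulation truth needs key '", key, "'", call. = FALSE)
    as.numeric(v)
  }
  sd <- num("noise_sd", 0)
  nRep <- as.integer(num("n_replicates", if (sd > 0) 10 else 1))
  scheme <- KineticScheme(kHOn = 0, kHOff = 0,
                          kPrimeO2 = num("k_prime_O2_uM_s"),
                          kO2Off = num("k_O2_off_s"),
                          kPrimeCO = num("k_prime_CO_uM_s"),
                          kCOOff = num("k_CO_off_s", 0))
  sf <- truth$stopped_flow %||% list()
  sfO2 <- as.numeric(sf$o2_uM %||% (o2Air / 2))
  sfCO <- as.numeric(sf$co_uM %||% 1000)
  coConcs <- as.numeric(truth$co_concs_uM %||% c(250, 500, 1000))
  kOx <- num("k_ox_per_h")

  simReps <- function(gen, seed0) {
    reps <- lapply(seq_len(nRep), function(r)
      gen(NoiseModel(sd, seed0 + r)))
    if (length(reps) == 1) reps[[1]] else averageTraces(reps)
  }
  flashO2 <- list(simReps(function(nm)
    flashPhotolysisTrace(scheme, "O2", conc = o2Air, basis = basis,
                         noise = nm), seed))
  flashCO <- lapply(seq_along(coConcs), function(j)
    simReps(function(nm)
      flashPhotolysisTrace(scheme, "CO", conc = coConcs[j], basis = basis,
                           monitorWavelength = 412, noise = nm),
      seed + 100L * j))
  stoppedFlow <- simReps(function(nm)
    stoppedFlowDisplacementTrace(scheme, o2Conc = sfO2, coConc = sfCO,
                                 basis = basis, noise = nm), seed + 17L)
  duration <- as.numeric(truth$autoox_duration_h %||% (4 * log(2) / kOx))
  autoox <- autoxidationSeries(kOx, duration = duration,
                               nSpectra = as.integer(num("autoox_n_spectra", 25)),
                               basis = basis,
                               noise = NoiseModel(sd, seed + 7000L))
  list(mode = "simulation",
       spectrum = equilibriumSpectrum(num("F_H"), basis = basis,
                                      noise = NoiseModel(sd, seed + 9000L)),
       flashO2 = flashO2, flashCO = flashCO, stoppedFlow = stoppedFlow,
       autooxSeries = autoox, kHOverride = NULL)
}

## ---- kinetic derivation ---------------------------------------------------

## From fitted observed rates to the binding constants. With a single O2
## flash concentration the TA and stopped-flow equations are solved jointly:
##   k_obs,TA = k'_O2 [O2]_TA + k_O2
##   k_O2     = k_obs,SF (1 + k'_O2 [O2]_SF / (k'_CO [CO]_SF))
## which is linear in k'_O2.
.deriveBinding <- function(inp, kH, o2Air, fits = function(f) NULL) {
  fitOne <- function(trace, label) {
    f <- fitSingleExponential(trace)
    fits(stats::setNames(list(list(kObs = f@kObs, se = f@seKObs, r2 = f@r2,
                                   accepted = f@accepted)), label))
    if (f@degenerate || !f@converged || !is.finite(f@kObs) || f@kObs <= 0)
      stop("exponential fit failed for ", label, call. = FALSE)
    f@kObs
  }
  if (!length(inp$flashO2)) stop("no O2 flash-photolysis traces", call. = FALSE)

  ## CO association rate from the concentration series
  kPrimeCO <- NA_real_
  if (length(inp$flashCO) >= 1) {
    coConc <- vapply(inp$flashCO, function(tr) tr@coConc, numeric(1))
    kObsCO <- vapply(seq_along(inp$flashCO), function(j)
      fitOne(inp$flashCO[[j]], sprintf("flash_CO_%g uM", coConc[j])), numeric(1))
    kPrimeCO <- if (length(unique(coConc)) >= 2)
      bimolecularRate(coConc, kObsCO)$kPrime
    else bimolecularRate(coConc, kObsCO, kOff = 0)$kPrime  # k_CO,off << k'CO[CO]
  }

  o2Conc <- vapply(inp$flashO2, function(tr) tr@o2Conc, numeric(1))
  kObsO2 <- vapply(seq_along(inp$flashO2), function(j)
    fitOne(inp$flashO2[[j]], sprintf("flash_O2_%g uM", o2Conc[j])), numeric(1))

  if (is.null(inp$stoppedFlow)) {
    if (length(unique(o2Conc)) < 2)
      stop("need a stopped-flow trace or >= 2 O2 concentrations", call. = FALSE)
    br <- bimolecularRate(o2Conc, kObsO2)
    return(bindingConstants(br$kPrime, br$kOffIntercept, kH,
                            kPrimeCOPent = kPrimeCO))
  }

  kObsSF <- fitOne(inp$stoppedFlow, "stopped_flow")
  sfO2 <- inp$stoppedFlow@o2Conc
  sfCO <- inp$stoppedFlow@coConc
  if (!is.finite(sfCO) || sfCO <= 0)
    stop("stopped-flow trace lacks its CO concentration", call. = FALSE)
  if (!is.finite(sfO2)) sfO2 <- 0

  if (length(unique(o2Conc)) >= 2) {
    kPrimeO2 <- bimolecularRate(o2Conc, kObsO2)$kPrime
  } else {
    if (!is.finite(kPrimeCO))
      stop("single-concentration O2 design needs the CO association rate",
           call. = FALSE)
    r <- sfO2 / (kPrimeCO * sfCO)
    kPrimeO2 <- (mean(kObsO2) - kObsSF) / (o2Conc[1] + kObsSF * r)
  }
  kO2 <- if (is.finite(kPrimeCO) && sfO2 > 0)
    correctO2Dissociation(kObsSF, kPrimeO2, kPrimeCO, sfO2, sfCO)
  else kObsSF
  bindingConstants(kPrimeO2, kO2, kH, kPrimeCOPent = kPrimeCO)
}

## ---- reporting ------------------------------------------------------------

#' Tabulate protein reports
#'
#' Collects a list of [ProteinReport-class] objects into the three result
#' tables: coordination (ratio, F_H, K_H), O2 binding (k'_O2,pent, k_O2,
#' K_O2,pent, K_O2) and autoxidation (k_ox, t_1/2), with units in the column
#' names.
#'
#' @param reports a list of [ProteinReport-class] objects.
#' @return a named list of three data.frames: `coordination`, `binding`,
#'   `autoox`.
#' @export
reportTables <- function(reports) {
  stopifnot(all(vapply(reports, is, logical(1), "ProteinReport")))
  pull <- function(extract, cols) {
    rows <- lapply(reports, extract)
    keep <- !vapply(rows, is.null, logical(1))
    if (!any(keep))
      return(stats::setNames(
        data.frame(matrix(nrow = 0, ncol = length(cols) + 1)),
        c("protein", cols)))
    do.call(rbind, rows[keep])
  }
  coordination <- pull(function(r) {
    if (is.null(r@coordination)) return(NULL)
    co <- r@coordination
    data.frame(protein = r@protein, ratio_A555_A540 = co@ratio,
               fraction_hexa = co@fh, K_H = co@kH,
               stringsAsFactors = FALSE)
  }, c("ratio_A555_A540", "fraction_hexa", "K_H"))
  binding <- pull(function(r) {
    if (is.null(r@binding)) return(NULL)
    b <- r@binding
    data.frame(protein = r@protein,
               k_prime_O2_pent_uM_s = b@kPrimeO2Pent, k_O2_s = b@kO2,
               k_prime_CO_pent_uM_s = b@kPrimeCOPent,
               K_O2_pent_uM = b@kO2Pent, K_O2_uM = b@kO2Eq, K_H = b@kH,
               stringsAsFactors = FALSE)
  }, c("k_prime_O2_pent_uM_s", "k_O2_s", "k_prime_CO_pent_uM_s",
       "K_O2_pent_uM", "K_O2_uM", "K_H"))
  autoox <- pull(function(r) {
    if (is.null(r@autoox)) return(NULL)
    a <- r@autoox
    data.frame(protein = r@protein, k_ox_per_h = a@kOx, t_half_min = a@tHalf,
               stringsAsFactors = FALSE)
  }, c("k_ox_per_h", "t_half_min"))
  list(coordination = coordination, binding = binding, autoox = autoox)
}

#' Write pipeline reports to disk
#'
#' Delimited format writes `coordination.csv`, `binding.csv` and
#' `autoox.csv` (numeric fields at 12 significant digits) plus a
#' machine-readable `run_log.json` holding every fitted parameter with its
#' standard error, per-protein errors and provenance. Human format writes a
#' single `report.txt`.
#'
#' @param reports a list of [ProteinReport-class] objects.
#' @param dir output directory (created if needed).
#' @param format `"delimited"` or `"human"`.
#' @return invisibly, the paths written.
#' @export
writeReport <- function(reports, dir, format = c("delimited", "human")) {
  format <- match.arg(format)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  tabs <- reportTables(reports)
  paths <- character()
  if (format == "delimited") {
    for (nm in names(tabs)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      df <- tabs[[nm]]
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
      utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
  } else {
    p <- file.path(dir, "report.txt")
    con <- file(p, "w")
    for (nm in names(tabs)) {
      writeLines(paste0("== ", nm, " =="), con)
      writeLines(utils::capture.output(print(tabs[[nm]], row.names = FALSE)), con)
      writeLines("", con)
    }
    close(con)
    paths <- c(paths, p)
  }
  log <- lapply(reports, function(r)
    list(protein = r@protein, errors = r@errors, provenance = r@provenance))
  lp <- file.path(dir, "run_log.json")
  jsonlite::write_json(log, lp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, lp))
}
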