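# Packaged reference data, delimited-text interfaces, run configuration and
# the end-to-end pipeline.

#' Read / write concentration series as delimited text
#'
#' Format: CSV with header `time_h,conc_nM,analyte`. Files holding several
#' analytes are split into one series per analyte.
#'
#' @param path file path.
#' @param provenance provenance flag for the series read.
#' @return `readConcentrationSeries`: named list of
#'   [ConcentrationSeries-class] (one per analyte).
#' @export
readConcentrationSeries <- function(path, provenance = "observed") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "conc_nM", "analyte")
  if (!all(need %in% names(df)))
    stop("expected header: time_h,conc_nM,analyte")
  out <- lapply(split(df, df$analyte), function(g) {
    g <- g[order(g$time_h), ]
    concentrationSeries(g$time_h, g$conc_nM, analyte = g$analyte[1],
                        provenance = provenance)
  })
  out[unique(df$analyte)]
}

#' @rdname readConcentrationSeries
#' @param series a [ConcentrationSeries-class] or list of them.
#' @export
writeConcentrationSeries <- function(series, path) {
  if (is(series, "ConcentrationSeries")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged in vivo free-plasma concentration series
#'
#' The 24-h free (unbound) mouse plasma concentration series for the ATM
#' inhibitor AZD0156 (10 mg/kg oral) and SN38 (active metabolite of 50 mg/kg
#' intraperitoneal irinotecan), sampled hourly, transcribed from the
#' platform's published reference table.
#'
#' @param analyte `"AZD0156"`, `"SN38"`, or `NULL` for both.
#' @return a [ConcentrationSeries-class], or a named list of both.
#' @export
referenceSeries <- function(analyte = NULL) {
  path <- system.file("extdata", "invivo_free_concentrations.csv",
                      package = "chipPKPD")
  all <- readConcentrationSeries(path, provenance = "observed")
  if (is.null(analyte)) return(all)
  if (!analyte %in% names(all))
    stop("analyte must be one of: ", paste(names(all), collapse = ", "))
  all[[analyte]]
}

#' Packaged reference reservoir schedule
#'
#' The transcribed 24-h stepwise reservoir schedule mimicking the in vivo
#' profiles: 7 drug steps on reservoirs 2-8 (reservoir 1 holds drug-free
#' medium), durations 1, 3, 2, 3, 3, 4 and 8 h.
#'
#' @param flowRate flow rate, uL/min.
#' @return an [ExposureSchedule-class] with both analytes.
#' @export
referenceSchedule <- function(flowRate = 20) {
  path <- system.file("extdata", "reservoir_schedule_reference.csv",
                      package = "chipPKPD")
  df <- read.csv(path, stringsAsFactors = FALSE)
  wide <- NULL
  for (a in unique(df$analyte)) {
    g <- df[df$analyte == a, c("reservoir", "start_h", "duration_h", "conc_nM")]
    names(g)[4] <- a
    wide <- if (is.null(wide)) g else merge(wide, g,
      by = c("reservoir", "start_h", "duration_h"))
  }
  wide <- wide[order(wide$start_h), ]
  rownames(wide) <- NULL
  new("ExposureSchedule", steps = wide,
      analytes = setdiff(names(wide), c("reservoir", "start_h", "duration_h")),
      cycleLength = sum(wide$duration_h), flowRate = flowRate)
}

#' Reference schedule interval boundaries
#'
#' Boundaries (h) of the transcribed reservoir schedule, on the clock of the
#' in vivo series (first sample at 1 h maps to schedule time 0 after
#' [prependZero()]).
#'
#' @return numeric vector `c(0, 1, 4, 6, 9, 12, 16, 24)`.
#' @export
referenceBoundaries <- function() {
  st <- steps(referenceSchedule())
  c(st$start_h, st$start_h[nrow(st)] + st$duration_h[nrow(st)])
}

#' Published percent growth inhibition reference values
#'
#' Percent growth inhibition (%GI) of treated versus control volumes for the
#' monotherapy and gapped combination schedules, in the perfused-chip
#' spheroid study (day 7) and the matching mouse xenograft study (day 15),
#' as published.
#'
#' @return data.frame with columns `setting`, `schedule`, `day`,
#'   `percent_gi`.
#' @export
referenceGrowthInhibition <- function() {
  read.csv(system.file("extdata", "growth_inhibition_reference.csv",
                       package = "chipPKPD"), stringsAsFactors = FALSE)
}

#' Gap-schedule %GI difference
#'
#' The difference in percent growth inhibition between the 24-h-gap and
#' 72-h-gap combination schedules, per experimental setting.
#'
#' @param gi data.frame as from [referenceGrowthInhibition()].
#' @return named numeric vector of `gi(gap24) - gi(gap72)` per setting.
#' @export
giGapDifference <- function(gi = referenceGrowthInhibition()) {
  vapply(split(gi, gi$setting), function(g) {
    g$percent_gi[g$schedule == "combo_gap24"] -
      g$percent_gi[g$schedule == "combo_gap72"]
  }, numeric(1))
}

#' Derive a module seed from the run seed
#'
#' One global seed fans out to per-module seeds by a fixed counter scheme
#' (`seed * 97 + counter`, reduced modulo 2^31 - 1), so each module remains
#' independently reproducible.
#'
#' @param seed global integer seed.
#' @param module module name (`"pd"`, `"imaging"`, `"pk"`, ...).
#' @return integer seed.
#' @export
moduleSeed <- function(seed, module) {
  counters <- c(pk = 1L, schedule = 2L, dilution = 3L, pd = 4L, imaging = 5L)
  ctr <- if (module %in% names(counters)) counters[[module]] else
    sum(utf8ToInt(module))
  as.integer((as.numeric(seed) * 97 + ctr) %% (2^31 - 1))
}

#' Read a pipeline run configuration
#'
#' YAML config with fields `regimen` (token), `n_steps`, `flow_rate`,
#' `seed`, `out_dir`, and optionally `series_file` (defaults to the packaged
#' reference series), `boundaries`, `peak_policy`, `stocks` (per-analyte
#' `conc` and `unit`) and `pd` overrides.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return named list (a run config).
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- list(regimen = "combo_7_7", n_steps = 8, flow_rate = 20,
              cycle_h = 24, cycle_days = 7, seed = 1, out_dir = "chip_run",
              series_file = NULL, boundaries = NULL, peak_policy = "mean",
              stocks = list(SN38 = list(conc = 0.1, unit = "mM"),
                            AZD0156 = list(conc = 1, unit = "mM")),
              pd = list())
  if (!is.null(path)) {
    if (!file.exists(path)) stop("missing input: ", path)
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  tokens <- c("mono", "combo_1_7", "combo_7_7", "combo_gap24", "combo_gap72")
  if (!cfg$regimen %in% tokens)
    stop("unknown regimen token '", cfg$regimen, "'; valid tokens: ",
         paste(tokens, collapse = ", "))
  num <- c("n_steps", "flow_rate", "cycle_h", "cycle_days", "seed")
  for (f in num) if (!isTRUE(cfg[[f]] > 0)) stop(f, " must be positive")
  cfg
}

#' Run the full schedule-design / dilution / simulation pipeline
#'
#' From the in vivo concentration series to a pump program, exposure
#' metrics, dilution worklists and a simulated spheroid growth response for
#' the configured regimen. All outputs are plain text; a manifest lists
#' every produced file with its MD5 content hash. Outputs are deterministic
#' for a fixed seed.
#'
#' @param config list from [readRunConfig()] (or a path to a YAML config).
#' @return invisibly, the manifest data.frame (`file`, `md5`).
#' @export
runPipeline <- function(config = readRunConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  series <- if (is.null(config$series_file)) referenceSeries()
            else readConcentrationSeries(config$series_file)
  series <- lapply(series, prependZero)

  schedules <- lapply(series, function(s)
    buildExposureSchedule(s,
      boundaries = config$boundaries, nSteps = config$n_steps,
      flowRate = config$flow_rate, peakPolicy = config$peak_policy))

  regimen <- regimenFromToken(config$regimen, cycleDays = config$cycle_days)
  timeline <- composeTreatmentTimeline(regimen, schedules)

  files <- character()
  # pump programs, one per dosed analyte
  for (a in unique(regimen@dosing$analyte)) {
    reg_a <- treatmentRegimen(regimen@dosing[regimen@dosing$analyte == a, ],
                              cycleDays = config$cycle_days)
    f <- file.path(out, sprintf("pump_program_%s.csv", a))
    writePumpProgram(schedules[[a]], reg_a, f)
    files <- c(files, f)
    fj <- file.path(out, sprintf("pump_program_%s.json", a))
    writePumpProgram(schedules[[a]], reg_a, fj, format = "json")
    files <- c(files, fj)
  }

  # exposure metrics: schedule vs source profile, plus static comparator
  met <- do.call(rbind, lapply(names(schedules), function(a) {
    sch_tl <- composeTreatmentTimeline(
      treatmentRegimen(data.frame(analyte = a, day = 1, mode = "pk_mimic"),
                       cycleDays = 1), schedules[a])
    m <- exposureMetrics(sch_tl, analyte = a, reference = series[[a]])
    ms <- exposureMetrics(series[[a]])
    stat <- staticTimeline(setNames(ms$Cmax, a), days = 1)
    mstat <- exposureMetrics(stat, analyte = a, reference = series[[a]])
    data.frame(analyte = a, profile_auc = ms$AUC, schedule_auc = m$AUC,
               schedule_mismatch = m$mismatch, static_auc = mstat$AUC,
               static_mismatch = mstat$mismatch, cmax = ms$Cmax,
               tmax = ms$Tmax)
  }))
  f <- file.path(out, "exposure_metrics.csv")
  write.csv(met, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  # dilution worklists
  plans <- lapply(names(schedules), function(a) {
    stk <- config$stocks[[a]]
    if (is.null(stk)) stk <- list(conc = 1, unit = "mM")
    st <- steps(schedules[[a]])
    planTwoStepDilution(stockSolution(a, stk$conc, stk$unit),
                        reservoirConcs = st[[a]],
                        reservoirVolumes = reservoirVolumeRequirement(
                          st$duration_h, config$flow_rate))
  })
  f <- file.path(out, "dilution_worklist.csv")
  writeWorklist(plans, f)
  files <- c(files, f)

  # PD simulation: configured regimen plus untreated control
  pd <- defaultPDParams()
  pd[names(config$pd)] <- config$pd
  horizon <- config$cycle_days
  ctrl <- simulateGrowth(pd, staticTimeline(c(SN38 = 0), horizon),
                         horizon = horizon)
  trt <- simulateGrowth(pd, timeline, horizon = horizon)
  if (isTRUE(pd$sigma > 0))
    trt <- observeVolumes(trt, pd$sigma, moduleSeed(config$seed, "pd"))
  f <- file.path(out, "growth_treated.csv")
  write.csv(as.data.frame(trt), f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  f <- file.path(out, "growth_control.csv")
  write.csv(as.data.frame(ctrl), f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  summ <- data.frame(
    regimen = config$regimen, seed = config$seed,
    relative_volume_pct = relativeVolume(trt, ctrl, t = horizon),
    percent_gi = percentGrowthInhibition(trt, ctrl, t = horizon))
  f <- file.path(out, "response_summary.csv")
  write.csv(summ, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(manifest)
}
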