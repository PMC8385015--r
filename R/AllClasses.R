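#' @import methods
#' @importFrom stats approx lm coef rnorm runif setNames optimize
#' @importFrom utils read.csv write.csv head tail
NULL

#' PKParams: one-compartment pharmacokinetic parameters
#'
#' Parameters of a one-compartment disposition model with either first-order
#' absorption (oral / intraperitoneal input) or bolus input. Concentrations are
#' free (unbound) plasma concentrations in nM, so `doseAmount / V` must be in
#' nM for the units to be consistent.
#'
#' @slot modelKind one of `"one_compartment_first_order_absorption"`,
#'   `"one_compartment_bolus"`.
#' @slot ka absorption rate constant (1/h). Must exceed `ke` (flip-flop is
#'   resolved by the constraint `ka > ke`).
#' @slot ke elimination rate constant (1/h).
#' @slot V apparent volume of distribution, in units such that `doseAmount/V`
#'   is nM.
#' @slot F bioavailable fraction in (0, 1].
#' @slot fu free (unbound) fraction in (0, 1].
#' @slot doseAmount administered amount (units consistent with `V`).
#' @seealso [pkParams()], [simulateProfile()], [fitPKParams()]
#' @exportClass PKParams
setClass("PKParams", representation(
  modelKind = "character",
  ka = "numeric", ke = "numeric", V = "numeric",
  F = "numeric", fu = "numeric", doseAmount = "numeric"
))

.pk_model_kinds <- c("one_compartment_first_order_absorption",
                     "one_compartment_bolus")

setValidity("PKParams", function(object) {
  msg <- character()
  if (!(object@modelKind %in% .pk_model_kinds))
    msg <- c(msg, sprintf("modelKind must be one of: %s",
                          paste(.pk_model_kinds, collapse = ", ")))
  if (!isTRUE(object@ke > 0)) msg <- c(msg, "ke must be > 0")
  if (object@modelKind == "one_compartment_first_order_absorption") {
    if (!isTRUE(object@ka > 0)) msg <- c(msg, "ka must be > 0")
    if (isTRUE(object@ka == object@ke))
      msg <- c(msg, "ka must differ from ke (degenerate closed form)")
    if (isTRUE(object@ka < object@ke))
      msg <- c(msg, "ka must exceed ke (flip-flop convention)")
  }
  if (!isTRUE(object@V > 0)) msg <- c(msg, "V must be > 0")
  if (!isTRUE(object@F > 0 && object@F <= 1)) msg <- c(msg, "F must be in (0, 1]")
  if (!isTRUE(object@fu > 0 && object@fu <= 1)) msg <- c(msg, "fu must be in (0, 1]")
  if (!isTRUE(object@doseAmount >= 0)) msg <- c(msg, "doseAmount must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ConcentrationSeries: a free-drug concentration versus time curve
#'
#' One analyte's free plasma (or medium) concentration sampled over time.
#' Linear interpolation between samples is assumed wherever the series is
#' treated as a continuous profile.
#'
#' @slot analyte analyte label, e.g. `"SN38"`.
#' @slot times sampling times in hours, strictly increasing.
#' @slot concentrations free concentrations in nM, non-negative, same length
#'   as `times`.
#' @slot provenance `"observed"` or `"simulated"`.
#' @seealso [concentrationSeries()], [intervalMean()], [equalAucBoundaries()]
#' @exportClass ConcentrationSeries
setClass("ConcentrationSeries", representation(
  analyte = "character", times = "numeric",
  concentrations = "numeric", provenance = "character"
))

setValidity("ConcentrationSeries", function(object) {
  msg <- character()
  if (length(object@times) != length(object@concentrations))
    msg <- c(msg, "times and concentrations must have equal length")
  if (length(object@times) && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(object@concentrations < 0))
    msg <- c(msg, "concentrations must be >= 0")
  if (!(object@provenance %in% c("observed", "simulated")))
    msg <- c(msg, "provenance must be 'observed' or 'simulated'")
  if (length(msg)) msg else TRUE
})

#' ExposureSchedule: timed piecewise-constant reservoir schedule
#'
#' An ordered set of reservoir steps covering one exposure cycle (24 h by
#' default). Each step delivers a constant concentration of each analyte for
#' its duration at the platform flow rate. Steps are contiguous: the first
#' starts at 0 h and each subsequent step starts where the previous one ends;
#' durations sum to the cycle length.
#'
#' @slot steps data.frame with columns `reservoir`, `start_h`, `duration_h`
#'   and one concentration column (nM) per analyte.
#' @slot analytes analyte labels; concentration columns in `steps` carry the
#'   same names.
#' @slot cycleLength cycle length in hours (default 24).
#' @slot flowRate delivery flow rate in microlitres per minute (default 20).
#' @seealso [buildExposureSchedule()], [referenceSchedule()],
#'   [composeTreatmentTimeline()]
#' @exportClass ExposureSchedule
setClass("ExposureSchedule", representation(
  steps = "data.frame", analytes = "character",
  cycleLength = "numeric", flowRate = "numeric"
))

setValidity("ExposureSchedule", function(object) {
  msg <- character()
  st <- object@steps
  need <- c("reservoir", "start_h", "duration_h", object@analytes)
  if (!all(need %in% names(st)))
    return(sprintf("steps must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(st) == 0) return("schedule must contain at least one step")
  if (any(st$duration_h <= 0)) msg <- c(msg, "step durations must be > 0")
  if (anyDuplicated(st$reservoir)) msg <- c(msg, "reservoir indices must be unique")
  for (a in object@analytes)
    if (any(st[[a]] < 0)) msg <- c(msg, sprintf("%s concentrations must be >= 0", a))
  tol <- 1e-8
  if (abs(st$start_h[1]) > tol) msg <- c(msg, "first step must start at 0 h")
  if (nrow(st) > 1) {
    gaps <- st$start_h[-1] - (st$start_h[-nrow(st)] + st$duration_h[-nrow(st)])
    if (any(abs(gaps) > tol)) msg <- c(msg, "steps must be contiguous")
  }
  if (abs(sum(st$duration_h) - object@cycleLength) > tol)
    msg <- c(msg, "durations must sum to cycleLength")
  if (!isTRUE(object@flowRate > 0)) msg <- c(msg, "flowRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' TreatmentRegimen: per-drug dosing-day pattern over a cycle
#'
#' Which days of the treatment cycle (default 7 days) each drug is dosed on,
#' and how it is delivered on those days (PK-mimicking stepped schedule or a
#' constant concentration).
#'
#' @slot cycleDays number of days in one cycle.
#' @slot dosing data.frame with columns `analyte`, `day` (1-based within the
#'   cycle) and `mode` (`"pk_mimic"` or `"static_constant"`).
#' @seealso [treatmentRegimen()], [regimenFromToken()]
#' @exportClass TreatmentRegimen
setClass("TreatmentRegimen", representation(
  cycleDays = "numeric", dosing = "data.frame"
))

setValidity("TreatmentRegimen", function(object) {
  msg <- character()
  d <- object@dosing
  if (!all(c("analyte", "day", "mode") %in% names(d)))
    return("dosing must have columns analyte, day, mode")
  if (!isTRUE(object@cycleDays >= 1)) msg <- c(msg, "cycleDays must be >= 1")
  if (nrow(d)) {
    if (any(d$day < 1 | d$day > object@cycleDays))
      msg <- c(msg, "dosing days must lie within [1, cycleDays]")
    if (!all(d$mode %in% c("pk_mimic", "static_constant")))
      msg <- c(msg, "mode must be 'pk_mimic' or 'static_constant'")
    if (anyDuplicated(d[c("analyte", "day")]))
      msg <- c(msg, "repeated dosing of one drug within one day is not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' TreatmentTimeline: per-drug piecewise-constant concentration over a cycle
#'
#' The concentration each drug sees on a shared clock across the whole
#' treatment cycle, as a piecewise-constant function: `conc[i, a]` holds
#' between `breaks[i]` and `breaks[i + 1]` for analyte `a`. Day 1 begins at
#' t = 0 h; intervals are half-open `[start, end)`.
#'
#' @slot analytes analyte labels (column names of `conc`).
#' @slot breaks strictly increasing breakpoints in hours, starting at 0.
#' @slot conc matrix of concentrations (nM), `length(breaks) - 1` rows.
#' @seealso [composeTreatmentTimeline()], [timelineConcentration()],
#'   [exposureMetrics()]
#' @exportClass TreatmentTimeline
setClass("TreatmentTimeline", representation(
  analytes = "character", breaks = "numeric", conc = "matrix"
))

setValidity("TreatmentTimeline", function(object) {
  msg <- character()
  if (length(object@breaks) < 2) msg <- c(msg, "need at least two breakpoints")
  if (any(diff(object@breaks) <= 0)) msg <- c(msg, "breaks must be strictly increasing")
  if (nrow(object@conc) != length(object@breaks) - 1)
    msg <- c(msg, "conc must have length(breaks) - 1 rows")
  if (!identical(colnames(object@conc), object@analytes))
    msg <- c(msg, "conc columns must match analytes")
  if (any(object@conc < 0)) msg <- c(msg, "concentrations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' DilutionPlan: stock to intermediate to reservoir dilution ledger
#'
#' The two-step dilution from a DMSO stock to per-reservoir working
#' concentrations: step 1 dispenses stock into intermediate aliquots, step 2
#' pipettes intermediate into each flow reservoir. Mass is conserved at every
#' transfer (volume x concentration).
#'
#' @slot analyte analyte label.
#' @slot stockConc stock concentration, nM.
#' @slot intermediateConc intermediate concentration, nM.
#' @slot aliquots data.frame describing step-1 aliquots (`aliquot`,
#'   `volume_uL`, `stock_uL`, `diluent_uL`).
#' @slot worklist data.frame with one row per transfer (`analyte`, `step`,
#'   `source`, `target`, `transfer_uL`, `final_conc_nM`).
#' @slot reservoirs data.frame with per-reservoir final concentration,
#'   volume, intermediate transfer volume and DMSO fraction.
#' @slot dmsoCap maximum tolerated DMSO volume fraction in a reservoir.
#' @seealso [planTwoStepDilution()], [writeWorklist()]
#' @exportClass DilutionPlan
setClass("DilutionPlan", representation(
  analyte = "character", stockConc = "numeric", intermediateConc = "numeric",
  aliquots = "data.frame", worklist = "data.frame", reservoirs = "data.frame",
  dmsoCap = "numeric"
))

#' GrowthTrajectory: simulated spheroid growth under a treatment timeline
#'
#' Output of the pharmacodynamic simulator: spheroid volume, the latent DNA
#' damage state and a viability proxy over time. Volumes are noise-free model
#' output; measurement noise is applied separately by [observeVolumes()].
#'
#' @slot times days from treatment start.
#' @slot volumes spheroid volume (same unit as the initial volume `V0`).
#' @slot damage latent damage state D(t) (unitless).
#' @slot viability viability proxy, relative units (1 at baseline).
#' @seealso [simulateGrowth()], [percentGrowthInhibition()], [relativeVolume()]
#' @exportClass GrowthTrajectory
setClass("GrowthTrajectory", representation(
  times = "numeric", volumes = "numeric", damage = "numeric",
  viability = "numeric"
))

setValidity("GrowthTrajectory", function(object) {
  n <- length(object@times)
  if (length(object@volumes) != n || length(object@damage) != n ||
      length(object@viability) != n)
    return("times, volumes, damage and viability must have equal length")
  if (any(object@volumes <= 0)) return("volumes must be > 0")
  TRUE
})

#' SpheroidImage: multichannel 2-D spheroid raster with optional ground truth
#'
#' A set of equally sized 2-D intensity rasters (brightfield plus fluorescence
#' channels) for one spheroid, with the physical pixel size. Synthetic images
#' carry ground truth (mask, nuclei centroids, per-marker positive labels)
#' used for benchmarking the quantification pipeline.
#'
#' @slot channels named list of numeric matrices, identical dimensions.
#'   Conventional names: `brightfield`, `nuclei`, `gammaH2AX`, `CC3`, `Ki67`.
#' @slot pixelSize microns per pixel.
#' @slot groundTruth list; for synthetic images holds `mask` (logical matrix),
#'   `centroids` (matrix, columns x/y in pixels), `positive` (named list of
#'   logical vectors per marker), `radius_um`, `nucleusRadius_um`.
#' @seealso [generateSyntheticSpheroid()], [segmentSpheroid()],
#'   [measureSpheroid()]
#' @exportClass SpheroidImage
setClass("SpheroidImage", representation(
  channels = "list", pixelSize = "numeric", groundTruth = "list"
))

setValidity("SpheroidImage", function(object) {
  msg <- character()
  if (!length(object@channels)) return("at least one channel required")
  dims <- lapply(object@channels, dim)
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), logical(1))))
    msg <- c(msg, "all channels must have identical dimensions")
  if (!isTRUE(object@pixelSize > 0)) msg <- c(msg, "pixelSize must be > 0")
  if (any(vapply(object@channels, function(ch) any(ch < 0), logical(1))))
    msg <- c(msg, "intensities must be >= 0")
  if (length(msg)) msg else TRUE
})
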