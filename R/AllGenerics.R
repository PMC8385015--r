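# Accessor generics. Plain functions would do, but generics keep the
# container API uniform across classes.

#' @rdname ConcentrationSeries-class
#' @param object,x an object.
#' @export
setGeneric("analyte", function(object) standardGeneric("analyte"))

#' @rdname ConcentrationSeries-class
#' @export
setGeneric("obsTimes", function(object) standardGeneric("obsTimes"))

#' @rdname ConcentrationSeries-class
#' @export
setGeneric("concentrations", function(object) standardGeneric("concentrations"))

#' @rdname ExposureSchedule-class
#' @export
setGeneric("steps", function(object) standardGeneric("steps"))

#' @rdname ExposureSchedule-class
#' @export
setGeneric("cycleLength", function(object) standardGeneric("cycleLength"))

#' @rdname ExposureSchedule-class
#' @export
setGeneric("flowRate", function(object) standardGeneric("flowRate"))

#' @rdname ExposureSchedule-class
#' @export
setGeneric("analytes", function(object) standardGeneric("analytes"))

#' @rdname SpheroidImage-class
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname SpheroidImage-class
#' @param name channel name.
#' @export
setGeneric("getChannel", function(object, name) standardGeneric("getChannel"))

#' @rdname SpheroidImage-class
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname SpheroidImage-class
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

setMethod("analyte", "ConcentrationSeries", function(object) object@analyte)
setMethod("obsTimes", "ConcentrationSeries", function(object) object@times)
setMethod("concentrations", "ConcentrationSeries",
          function(object) object@concentrations)

setMethod("steps", "ExposureSchedule", function(object) object@steps)
setMethod("cycleLength", "ExposureSchedule", function(object) object@cycleLength)
setMethod("flowRate", "ExposureSchedule", function(object) object@flowRate)
setMethod("analytes", "ExposureSchedule", function(object) object@analytes)
setMethod("analytes", "TreatmentTimeline", function(object) object@analytes)

setMethod("channelNames", "SpheroidImage", function(object) names(object@channels))
setMethod("getChannel", "SpheroidImage", function(object, name) {
  if (!name %in% names(object@channels))
    stop("no such channel: ", name)
  object@channels[[name]]
})
setMethod("pixelSize", "SpheroidImage", function(object) object@pixelSize)
setMethod("groundTruth", "SpheroidImage", function(object) object@groundTruth)

#' @describeIn ConcentrationSeries-class number of samples
#' @export
setMethod("length", "ConcentrationSeries", function(x) length(x@times))

#' @describeIn ConcentrationSeries-class as `data.frame` with columns
#'   `time_h`, `conc_nM`, `analyte`
#' @param row.names,optional,... passed on conventions of [as.data.frame()].
#' @export
setMethod("as.data.frame", "ConcentrationSeries",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(time_h = x@times, conc_nM = x@concentrations,
               analyte = x@analyte, stringsAsFactors = FALSE)
  })

setMethod("show", "ConcentrationSeries", function(object) {
  cat(sprintf("ConcentrationSeries '%s' (%s): %d samples over [%g, %g] h, Cmax %g nM\n",
              object@analyte, object@provenance, length(object@times),
              min(object@times), max(object@times),
              if (length(object@concentrations)) max(object@concentrations) else NA))
})

setMethod("show", "ExposureSchedule", function(object) {
  cat(sprintf("ExposureSchedule: %d steps over %g h at %g uL/min; analytes: %s\n",
              nrow(object@steps), object@cycleLength, object@flowRate,
              paste(object@analytes, collapse = ", ")))
  print(object@steps, row.names = FALSE)
})

setMethod("show", "TreatmentRegimen", function(object) {
  cat(sprintf("TreatmentRegimen over %d-day cycle:\n", object@cycleDays))
  if (nrow(object@dosing)) {
    for (a in unique(object@dosing$analyte)) {
      d <- object@dosing[object@dosing$analyte == a, ]
      cat(sprintf("  %s: day(s) %s (%s)\n", a,
                  paste(sort(d$day), collapse = ","),
                  paste(unique(d$mode), collapse = "/")))
    }
  } else cat("  (no dosing)\n")
})

setMethod("show", "TreatmentTimeline", function(object) {
  cat(sprintf("TreatmentTimeline: %d segments over [0, %g] h; analytes: %s\n",
              nrow(object@conc), max(object@breaks),
              paste(object@analytes, collapse = ", ")))
})

setMethod("show", "DilutionPlan", function(object) {
  cat(sprintf("DilutionPlan for %s: stock %g nM -> intermediate %g nM -> %d reservoir(s)\n",
              object@analyte, object@stockConc, object@intermediateConc,
              nrow(object@reservoirs)))
})

setMethod("show", "GrowthTrajectory", function(object) {
  cat(sprintf("GrowthTrajectory: %d points over [%g, %g] days; V(end)/V(0) = %.3g\n",
              length(object@times), min(object@times), max(object@times),
              object@volumes[length(object@volumes)] / object@volumes[1]))
})

setMethod("show", "SpheroidImage", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("SpheroidImage: %d channel(s) [%s], %d x %d px at %g um/px%s\n",
              length(object@channels),
              paste(names(object@channels), collapse = ", "),
              d[1], d[2], object@pixelSize,
              if (length(object@groundTruth)) " (with ground truth)" else ""))
})

#' @describeIn GrowthTrajectory-class as `data.frame` with columns `day`,
#'   `volume`, `damage`, `viability`
#' @param x,row.names,optional,... standard [as.data.frame()] arguments.
#' @export
setMethod("as.data.frame", "GrowthTrajectory",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(day = x@times, volume = x@volumes, damage = x@damage,
               viability = x@viability)
  })
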