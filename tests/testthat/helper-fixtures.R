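# Shared fixtures built in code.

# finely sampled exponential-decay profile C(t) = c0 * exp(-ke * t)
expDecaySeries <- function(ke = 0.2, c0 = 1, tmax = 24, dt = 0.01) {
  t <- seq(0, tmax, by = dt)
  concentrationSeries(t, c0 * exp(-ke * t), analyte = "drug")
}

# rasterized ellipse mask (axis-aligned semi-axes a, b px, rotated by theta)
ellipseMask <- function(a, b = a, thetaDeg = 0, pad = 10) {
  half <- ceiling(max(a, b) + pad)
  n <- 2 * half + 1
  th <- thetaDeg * pi / 180
  col0 <- matrix(rep(0:(n - 1), each = n), n)
  row0 <- matrix(rep(0:(n - 1), times = n), n)
  xr <- (col0 - half) * cos(th) + (row0 - half) * sin(th)
  yr <- -(col0 - half) * sin(th) + (row0 - half) * cos(th)
  (xr / a)^2 + (yr / b)^2 <= 1
}

# recall / precision of detected vs true centroids at a match radius
matchCentroids <- function(detected, truth, radius) {
  if (!nrow(detected) || !nrow(truth))
    return(c(recall = 0, precision = 0))
  d2 <- outer(detected[, 1], truth[, 1], "-")^2 +
    outer(detected[, 2], truth[, 2], "-")^2
  c(recall = mean(apply(d2, 2, min) <= radius^2),
    precision = mean(apply(d2, 1, min) <= radius^2))
}

# single-dose schedules for both packaged analytes, equal-AUC, 8 steps
referenceEqualAucSchedules <- function(nSteps = 8) {
  lapply(lapply(referenceSeries(), prependZero),
         buildExposureSchedule, nSteps = nSteps)
}

# step timeline covering one day from a schedule for one analyte
oneDayTimeline <- function(schedule, analyte) {
  composeTreatmentTimeline(
    treatmentRegimen(data.frame(analyte = analyte, day = 1,
                                mode = "pk_mimic"), cycleDays = 1),
    setNames(list(schedule), analyte))
}
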