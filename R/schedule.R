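# Discretisation of a continuous PK profile into a timed reservoir schedule,
# treatment-timeline composition, and exposure metrics.

# Linear interpolation of a series at times tt; no extrapolation.
.series_interp <- function(series, tt) {
  rng <- range(series@times)
  if (any(tt < rng[1] - 1e-12 | tt > rng[2] + 1e-12))
    stop(sprintf("time outside series support [%g, %g] h", rng[1], rng[2]))
  approx(series@times, series@concentrations, xout = tt, rule = 1)$y
}

#' Prepend a zero sample at t = 0 to a post-dose series
#'
#' Tabulated post-dose profiles often start at the first sampling time (1 h
#' here); for schedule design the pre-dose concentration is taken as 0 nM at
#' t = 0. No-op if the series already starts at 0.
#'
#' @param series a [ConcentrationSeries-class].
#' @param t0 time of the prepended zero sample (default 0 h).
#' @return a [ConcentrationSeries-class].
#' @export
prependZero <- function(series, t0 = 0) {
  if (series@times[1] <= t0) return(series)
  concentrationSeries(c(t0, series@times), c(0, series@concentrations),
                      analyte = series@analyte, provenance = series@provenance)
}

#' Time-weighted mean concentration over an interval
#'
#' `(1/(t1 - t0))` times the trapezoidal integral of the linearly
#' interpolated series over `[t0, t1]`. Exact for the piecewise-linear
#' profile (interval endpoints are inserted by interpolation).
#'
#' @param series a [ConcentrationSeries-class].
#' @param t0,t1 interval bounds in hours, `t0 < t1`, inside the series
#'   support.
#' @return mean concentration, nM.
#' @examples
#' s <- concentrationSeries(0:10, seq(10, 0, by = -1))
#' intervalMean(s, 0, 10)  # 5
#' @export
intervalMean <- function(series, t0, t1) {
  if (!(t0 < t1)) stop("require t0 < t1")
  knots <- series@times[series@times > t0 & series@times < t1]
  tt <- c(t0, knots, t1)
  cc <- .series_interp(series, tt)
  sum(diff(tt) * (head(cc, -1) + tail(cc, -1)) / 2) / (t1 - t0)
}

# Cumulative trapezoidal AUC of a series evaluated at its own knots.
.cum_auc <- function(series) {
  t <- series@times; c <- series@concentrations
  c(0, cumsum(diff(t) * (head(c, -1) + tail(c, -1)) / 2))
}

#' Equal-AUC interval boundaries for schedule discretisation
#'
#' Partitions the series support into `nSteps` intervals of equal area under
#' the (linearly interpolated) curve. Within each knot interval the
#' cumulative AUC is quadratic in time, so boundaries are solved exactly.
#'
#' @param series a [ConcentrationSeries-class] with positive total AUC.
#' @param nSteps number of intervals (>= 1).
#' @return numeric vector of `nSteps + 1` strictly increasing boundaries
#'   (h), starting and ending at the series support ends.
#' @examples
#' s <- concentrationSeries(seq(0, 24, 0.1), rep(1, 241))
#' equalAucBoundaries(s, 4)  # 0, 6, 12, 18, 24
#' @export
equalAucBoundaries <- function(series, nSteps = 8) {
  if (nSteps < 1) stop("nSteps must be >= 1")
  cum <- .cum_auc(series)
  total <- cum[length(cum)]
  if (total <= 0) stop("series AUC must be > 0 (all-zero series rejected)")
  targets <- total * seq_len(nSteps - 1) / nSteps
  t <- series@times; cc <- series@concentrations
  inner <- vapply(targets, function(tg) {
    i <- findInterval(tg, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(t) - 1L)
    # solve cum[i] + c_i*x + s_i*x^2/2 = tg on [0, dt]
    dt <- t[i + 1] - t[i]
    ci <- cc[i]; si <- (cc[i + 1] - cc[i]) / dt
    rem <- tg - cum[i]
    x <- if (abs(si) < 1e-14) {
      if (ci <= 0) dt / 2 else rem / ci
    } else {
      disc <- ci^2 + 2 * si * rem
      (-ci + sqrt(max(disc, 0))) / si
    }
    t[i] + min(max(x, 0), dt)
  }, numeric(1))
  b <- c(t[1], inner, t[length(t)])
  if (any(diff(b) <= 0))
    stop("degenerate boundaries (flat-zero stretches in the profile)")
  b
}

#' Build a stepwise reservoir exposure schedule from PK profiles
#'
#' One reservoir step per boundary interval; each step's concentration per
#' analyte is the time-weighted interval mean of that analyte's profile
#' ([intervalMean()]), rounded to 3 significant figures. With
#' `peakPolicy = "cmax"` the step whose interval contains an analyte's Tmax
#' is instead anchored at the profile maximum (Cmax), matching how the
#' platform's first reservoir is conventionally set; note this policy no
#' longer preserves the profile AUC exactly. The schedule clock starts at the
#' first boundary.
#'
#' @param series a [ConcentrationSeries-class] or a named list of them (one
#'   per analyte). Multiple series must share the same time support.
#' @param boundaries optional strictly increasing boundary vector (h) inside
#'   the common support; default: equal-AUC boundaries ([equalAucBoundaries()])
#'   of the first series.
#' @param nSteps number of steps when `boundaries` is not supplied.
#' @param flowRate delivery flow rate, uL/min.
#' @param peakPolicy `"mean"` (default) or `"cmax"`, see above.
#' @param reservoirs optional reservoir indices, one per step (default
#'   `1:nSteps`).
#' @param sigfig significant figures for step concentrations (default 3).
#' @return an [ExposureSchedule-class].
#' @examples
#' s <- prependZero(referenceSeries("SN38"))
#' buildExposureSchedule(s, nSteps = 8)
#' @export
buildExposureSchedule <- function(series, boundaries = NULL, nSteps = 8,
                                  flowRate = 20,
                                  peakPolicy = c("mean", "cmax"),
                                  reservoirs = NULL, sigfig = 3) {
  peakPolicy <- match.arg(peakPolicy)
  if (is(series, "ConcentrationSeries")) {
    series <- setNames(list(series), series@analyte)
  }
  if (is.null(names(series)) || any(!nzchar(names(series))))
    names(series) <- vapply(series, analyte, character(1))
  supports <- lapply(series, function(s) range(s@times))
  if (!all(vapply(supports, function(r) isTRUE(all.equal(r, supports[[1]])),
                  logical(1))))
    stop("analyte series have differing time supports; resample to a common support")
  if (is.null(boundaries)) boundaries <- equalAucBoundaries(series[[1]], nSteps)
  if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly increasing")
  rng <- supports[[1]]
  if (boundaries[1] < rng[1] - 1e-9 ||
      boundaries[length(boundaries)] > rng[2] + 1e-9)
    stop("boundaries must lie within the series support")
  n <- length(boundaries) - 1L
  if (is.null(reservoirs)) reservoirs <- seq_len(n)
  if (length(reservoirs) != n) stop("need one reservoir index per step")

  st <- data.frame(reservoir = reservoirs,
                   start_h = boundaries[-length(boundaries)] - boundaries[1],
                   duration_h = diff(boundaries))
  for (a in names(series)) {
    s <- series[[a]]
    conc <- vapply(seq_len(n), function(i)
      intervalMean(s, boundaries[i], boundaries[i + 1]), numeric(1))
    if (peakPolicy == "cmax") {
      tmax <- s@times[which.max(s@concentrations)]
      hit <- which(tmax >= boundaries[-length(boundaries)] - 1e-9 &
                   tmax < boundaries[-1] + 1e-9)[1]
      conc[hit] <- max(s@concentrations)
    }
    st[[a]] <- signif(conc, sigfig)
  }
  new("ExposureSchedule", steps = st, analytes = names(series),
      cycleLength = boundaries[length(boundaries)] - boundaries[1],
      flowRate = flowRate)
}

#' Construct a treatment regimen
#'
#' @param dosing data.frame with columns `analyte`, `day`, `mode`; see
#'   [TreatmentRegimen-class].
#' @param cycleDays days per cycle (default 7).
#' @return a [TreatmentRegimen-class].
#' @export
treatmentRegimen <- function(dosing, cycleDays = 7) {
  if (!"mode" %in% names(dosing)) dosing$mode <- "pk_mimic"
  new("TreatmentRegimen", cycleDays = cycleDays,
      dosing = as.data.frame(dosing, stringsAsFactors = FALSE))
}

#' Standard regimen tokens
#'
#' Builds the study's treatment regimens from their shorthand tokens over a
#' 7-day cycle: `mono` (SN38 day 1), `combo_1_7` (SN38 day 1 + ATMi day 1),
#' `combo_7_7` (SN38 day 1 + ATMi days 1-7), `combo_gap24` (ATMi days 2-4,
#' i.e. starting 24 h after SN38) and `combo_gap72` (ATMi days 4-6, 72 h
#' gap).
#'
#' @param token one of `"mono"`, `"combo_1_7"`, `"combo_7_7"`,
#'   `"combo_gap24"`, `"combo_gap72"`.
#' @param drug primary drug label (default `"SN38"`).
#' @param partner combination partner label (default `"AZD0156"`).
#' @param cycleDays days per cycle (default 7).
#' @return a [TreatmentRegimen-class].
#' @export
regimenFromToken <- function(token, drug = "SN38", partner = "AZD0156",
                             cycleDays = 7) {
  tokens <- c("mono", "combo_1_7", "combo_7_7", "combo_gap24", "combo_gap72")
  if (!token %in% tokens)
    stop("unknown regimen token '", token, "'; valid tokens: ",
         paste(tokens, collapse = ", "))
  partner_days <- switch(token,
    mono = integer(0), combo_1_7 = 1L, combo_7_7 = 1:7,
    combo_gap24 = 2:4, combo_gap72 = 4:6)
  dosing <- data.frame(analyte = c(drug, rep(partner, length(partner_days))),
                       day = c(1L, partner_days), mode = "pk_mimic",
                       stringsAsFactors = FALSE)
  treatmentRegimen(dosing, cycleDays = cycleDays)
}

#' Compose per-drug concentration timelines over a full treatment cycle
#'
#' Places each drug's 24-h exposure schedule at the start of each of its
#' dosing days (day d starts at `(d-1) * 24` h) and zero concentration
#' elsewhere; drugs share a common clock. Days dosed in `static_constant`
#' mode deliver the schedule's maximum step concentration for the whole day.
#'
#' @param regimen a [TreatmentRegimen-class].
#' @param schedules named list of [ExposureSchedule-class], one per dosed
#'   analyte.
#' @return a [TreatmentTimeline-class] spanning `[0, cycleDays * 24]` h.
#' @export
composeTreatmentTimeline <- function(regimen, schedules) {
  stopifnot(is(regimen, "TreatmentRegimen"))
  validObject(regimen)
  horizon <- regimen@cycleDays * 24
  dosed <- unique(regimen@dosing$analyte)
  missing_s <- setdiff(dosed, names(schedules))
  if (length(missing_s))
    stop("no exposure schedule supplied for: ", paste(missing_s, collapse = ", "))
  segs <- list()
  for (i in seq_len(nrow(regimen@dosing))) {
    a <- regimen@dosing$analyte[i]
    day <- regimen@dosing$day[i]
    sch <- schedules[[a]]
    off <- (day - 1) * 24
    if (sch@cycleLength > 24 + 1e-9)
      stop("per-day schedules longer than 24 h cannot be tiled daily")
    if (regimen@dosing$mode[i] == "static_constant") {
      segs[[length(segs) + 1L]] <- data.frame(
        analyte = a, start = off, end = off + 24,
        conc = max(sch@steps[[a]]))
    } else {
      segs[[length(segs) + 1L]] <- data.frame(
        analyte = a, start = off + sch@steps$start_h,
        end = off + sch@steps$start_h + sch@steps$duration_h,
        conc = sch@steps[[a]])
    }
  }
  segs <- if (length(segs)) do.call(rbind, segs) else
    data.frame(analyte = character(), start = numeric(), end = numeric(),
               conc = numeric())
  all_analytes <- sort(unique(c(dosed, names(schedules))))
  breaks <- sort(c(0, horizon, segs$start, segs$end))
  breaks <- breaks[breaks >= 0 & breaks <= horizon]
  breaks <- breaks[c(TRUE, diff(breaks) > 1e-9)]  # drop fp-near duplicates
  conc <- matrix(0, nrow = length(breaks) - 1, ncol = length(all_analytes),
                 dimnames = list(NULL, all_analytes))
  mid <- (head(breaks, -1) + tail(breaks, -1)) / 2
  for (j in seq_len(nrow(segs))) {
    rows <- mid >= segs$start[j] & mid < segs$end[j]
    conc[rows, segs$analyte[j]] <- conc[rows, segs$analyte[j]] + segs$conc[j]
  }
  new("TreatmentTimeline", analytes = all_analytes, breaks = breaks,
      conc = conc)
}

#' Constant-concentration ("static plate") timeline
#'
#' @param conc named vector of constant concentrations (nM) per analyte.
#' @param days exposure duration in days.
#' @return a [TreatmentTimeline-class].
#' @examples
#' staticTimeline(c(SN38 = 5.5), days = 6)
#' @export
staticTimeline <- function(conc, days) {
  a <- names(conc)
  if (is.null(a)) stop("conc must be a named vector")
  m <- matrix(conc, nrow = 1, dimnames = list(NULL, a))
  new("TreatmentTimeline", analytes = a, breaks = c(0, days * 24), conc = m)
}

#' Evaluate a timeline's concentration at given times
#'
#' @param timeline a [TreatmentTimeline-class].
#' @param analyte analyte label.
#' @param t times in hours (values beyond the timeline evaluate to 0;
#'   intervals are half-open `[start, end)`).
#' @return concentrations, nM.
#' @export
timelineConcentration <- function(timeline, analyte, t) {
  if (!analyte %in% timeline@analytes) stop("unknown analyte: ", analyte)
  idx <- findInterval(t, timeline@breaks, left.open = FALSE)
  out <- numeric(length(t))
  ok <- idx >= 1 & idx <= nrow(timeline@conc) & t >= timeline@breaks[1]
  out[ok] <- timeline@conc[idx[ok], analyte]
  out
}

# Elementary segments (start, end, value at both ends) of a profile:
# step timelines give constant segments, series give linear ones.
.profile_segments <- function(x, analyte = NULL) {
  if (is(x, "TreatmentTimeline")) {
    if (is.null(analyte)) {
      if (length(x@analytes) != 1)
        stop("specify `analyte` for a multi-drug timeline")
      analyte <- x@analytes
    }
    v <- x@conc[, analyte]
    data.frame(t0 = head(x@breaks, -1), t1 = tail(x@breaks, -1),
               c0 = v, c1 = v)
  } else if (is(x, "ConcentrationSeries")) {
    t <- x@times; v <- x@concentrations
    data.frame(t0 = head(t, -1), t1 = tail(t, -1),
               c0 = head(v, -1), c1 = tail(v, -1))
  } else stop("x must be a TreatmentTimeline or ConcentrationSeries")
}

# integral of |f - g| where both are piecewise linear over shared breakpoints
.abs_diff_integral <- function(segA, segB) {
  bks <- sort(unique(c(segA$t0, segA$t1, segB$t0, segB$t1)))
  lo <- max(min(segA$t0), min(segB$t0))
  hi <- min(max(segA$t1), max(segB$t1))
  bks <- bks[bks >= lo & bks <= hi]
  evalseg <- function(seg, tt, side) {
    i <- findInterval(tt, c(seg$t0, seg$t1[nrow(seg)]),
                      rightmost.closed = TRUE, left.open = (side == "left"))
    i <- pmin(pmax(i, 1L), nrow(seg))
    w <- (tt - seg$t0[i]) / (seg$t1[i] - seg$t0[i])
    seg$c0[i] + w * (seg$c1[i] - seg$c0[i])
  }
  total <- 0
  for (k in seq_len(length(bks) - 1)) {
    a <- bks[k]; b <- bks[k + 1]
    # evaluate each function just inside the interval to dodge jumps
    d0 <- evalseg(segA, a, "right") - evalseg(segB, a, "right")
    d1 <- evalseg(segA, b, "left") - evalseg(segB, b, "left")
    w <- b - a
    if (d0 * d1 >= 0) {
      total <- total + w * (abs(d0) + abs(d1)) / 2
    } else {
      xc <- d0 / (d0 - d1)  # linear crossing
      total <- total + w * (xc * abs(d0) + (1 - xc) * abs(d1)) / 2
    }
  }
  total
}

#' Exposure metrics of a concentration profile
#'
#' AUC (trapezoid), Cmax, Tmax (earliest on ties), time above a threshold
#' (linear interpolation of crossings for sampled series; exact interval
#' measure for step timelines) and, when a reference profile is supplied, the
#' mismatch `integral of |profile - reference|` over the overlap of their
#' supports.
#'
#' @param x a [TreatmentTimeline-class] or [ConcentrationSeries-class].
#' @param analyte analyte to evaluate (required for multi-drug timelines).
#' @param reference optional reference [ConcentrationSeries-class] (or
#'   single-analyte timeline).
#' @param threshold optional non-negative threshold (nM) for `timeAbove`.
#' @return list with `AUC` (nM h), `Cmax` (nM), `Tmax` (h), `timeAbove` (h,
#'   `NA` if no threshold given) and `mismatch` (nM h, `NA` without
#'   reference).
#' @examples
#' tl <- staticTimeline(c(SN38 = 5.5), days = 6)
#' exposureMetrics(tl)$AUC  # 792
#' @export
exposureMetrics <- function(x, analyte = NULL, reference = NULL,
                            threshold = NULL) {
  seg <- .profile_segments(x, analyte)
  w <- seg$t1 - seg$t0
  auc <- sum(w * (seg$c0 + seg$c1) / 2)
  cmax <- max(seg$c0, seg$c1)
  # earliest time attaining the max
  hit <- which(seg$c0 == cmax | seg$c1 == cmax)[1]
  tmax <- if (seg$c0[hit] == cmax) seg$t0[hit] else seg$t1[hit]
  timeAbove <- NA_real_
  if (!is.null(threshold)) {
    if (threshold < 0) stop("threshold must be >= 0")
    timeAbove <- sum(vapply(seq_len(nrow(seg)), function(i) {
      c0 <- seg$c0[i]; c1 <- seg$c1[i]; wi <- w[i]
      if (c0 > threshold && c1 > threshold) return(wi)
      if (c0 <= threshold && c1 <= threshold) return(0)
      frac <- abs((max(c0, c1) - threshold) / (c1 - c0))
      wi * frac
    }, numeric(1)))
  }
  mismatch <- NA_real_
  if (!is.null(reference))
    mismatch <- .abs_diff_integral(seg, .profile_segments(reference))
  list(AUC = auc, Cmax = cmax, Tmax = tmax, timeAbove = timeAbove,
       mismatch = mismatch)
}

#' Write / read a pump program
#'
#' Serialises an exposure schedule under a regimen as one record per
#' reservoir switch per dosed analyte-day: columns `day`, `reservoir`,
#' `start_h` (within the day), `duration_h`, `analyte`, `conc_nM`,
#' `flow_uL_min`. `format = "json"` writes the same records as a structured
#' document with one concentration map per switch. The pair round-trips
#' losslessly.
#'
#' @param schedule an [ExposureSchedule-class].
#' @param regimen a [TreatmentRegimen-class].
#' @param path output file; with `NULL` the record data.frame is returned
#'   only.
#' @param format `"csv"` or `"json"`.
#' @return the records data.frame, invisibly when written to a file.
#' @export
writePumpProgram <- function(schedule, regimen, path = NULL,
                             format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is(schedule, "ExposureSchedule"), is(regimen, "TreatmentRegimen"))
  validObject(schedule); validObject(regimen)
  recs <- list()
  for (i in seq_len(nrow(regimen@dosing))) {
    a <- regimen@dosing$analyte[i]
    if (!a %in% schedule@analytes)
      stop("schedule has no concentrations for analyte ", a)
    day <- regimen@dosing$day[i]
    recs[[length(recs) + 1L]] <- data.frame(
      day = day, reservoir = schedule@steps$reservoir,
      start_h = schedule@steps$start_h,
      duration_h = schedule@steps$duration_h,
      analyte = a, conc_nM = schedule@steps[[a]],
      flow_uL_min = schedule@flowRate, stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, recs)
  recs <- recs[order(recs$day, recs$start_h, recs$analyte), , drop = FALSE]
  rownames(recs) <- NULL
  if (is.null(path)) return(recs)
  if (format == "csv") {
    write.csv(recs, path, row.names = FALSE, quote = FALSE)
  } else {
    key <- interaction(recs$day, recs$start_h, drop = TRUE)
    out <- lapply(split(recs, key), function(g) {
      list(cycle_day = g$day[1], reservoir_index = g$reservoir[1],
           start_h = g$start_h[1], duration_h = g$duration_h[1],
           conc_nM = as.list(setNames(g$conc_nM, g$analyte)),
           flow_uL_min = g$flow_uL_min[1])
    })
    names(out) <- NULL
    jsonlite::write_json(list(records = out), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(recs)
}

#' @rdname writePumpProgram
#' @export
readPumpProgram <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    lines <- readLines(path)
    hdr <- strsplit(lines[1], ",")[[1]]
    need <- c("day", "reservoir", "start_h", "duration_h", "analyte",
              "conc_nM", "flow_uL_min")
    if (!identical(hdr, need))
      stop("malformed pump program header at line 1")
    rows <- lapply(seq_along(lines)[-1], function(i) {
      f <- strsplit(lines[i], ",")[[1]]
      if (length(f) != 7)
        stop(sprintf("malformed pump program record at line %d", i))
      num <- suppressWarnings(as.numeric(f[c(1:4, 6:7)]))
      if (any(is.na(num)))
        stop(sprintf("non-numeric field in pump program at line %d", i))
      data.frame(day = num[1], reservoir = num[2], start_h = num[3],
                 duration_h = num[4], analyte = f[5], conc_nM = num[5],
                 flow_uL_min = num[6], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    doc <- jsonlite::read_json(path)
    rows <- lapply(doc$records, function(r) {
      data.frame(day = r$cycle_day, reservoir = r$reservoir_index,
                 start_h = r$start_h, duration_h = r$duration_h,
                 analyte = names(r$conc_nM),
                 conc_nM = unlist(r$conc_nM, use.names = FALSE),
                 flow_uL_min = r$flow_uL_min, stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, rows)
    recs <- recs[order(recs$day, recs$start_h, recs$analyte), , drop = FALSE]
    rownames(recs) <- NULL
    recs
  }
}
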