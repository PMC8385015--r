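test_that("interval mean is exact on constant and linear profiles", {
  const <- concentrationSeries(seq(0, 24, 0.5), rep(7, 49))
  expect_equal(intervalMean(const, 2, 9.5), 7)
  lin <- concentrationSeries(0:10, seq(10, 0, by = -1))
  expect_equal(intervalMean(lin, 0, 10), 5)
  expect_error(intervalMean(lin, -1, 5), "support")
  expect_error(intervalMean(lin, 5, 5), "t0 < t1")
})

test_that("interval mean matches a fine-grid Riemann oracle on packaged data", {
  s <- referenceSeries("SN38")
  t0 <- 1; t1 <- 2
  dt <- 0.001
  mids <- seq(t0 + dt / 2, t1 - dt / 2, by = dt)
  oracle <- mean(approx(obsTimes(s), concentrations(s), xout = mids)$y)
  got <- intervalMean(s, t0, t1)
  expect_lt(abs(got - oracle) / oracle, 1e-6)
  in_window <- concentrations(s)[obsTimes(s) >= t0 & obsTimes(s) <= t1]
  expect_gte(got, min(in_window))
  expect_lte(got, max(in_window))
})

test_that("equal-AUC boundaries are uniform on a constant profile", {
  const <- concentrationSeries(seq(0, 24, 0.1), rep(3, 241))
  expect_equal(equalAucBoundaries(const, 4), c(0, 6, 12, 18, 24),
               tolerance = 1e-9)
  expect_equal(equalAucBoundaries(const, 1), c(0, 24))
  expect_error(equalAucBoundaries(concentrationSeries(0:5, rep(0, 6)), 4),
               "AUC")
})

test_that("equal-AUC boundaries match exponential closed-form quantiles", {
  ke <- 0.2; tmax <- 24
  s <- expDecaySeries(ke = ke, tmax = tmax)
  n <- 8
  b <- equalAucBoundaries(s, n)
  total <- 1 - exp(-ke * tmax)
  analytic <- -log(1 - total * (0:n) / n) / ke
  expect_equal(b, analytic, tolerance = 1e-4)
})

test_that("schedule steps respect the invariants and conserve AUC", {
  s <- prependZero(referenceSeries("AZD0156"))
  sch <- buildExposureSchedule(s, nSteps = 8)
  st <- steps(sch)
  expect_equal(sum(st$duration_h), cycleLength(sch))
  expect_equal(st$start_h[1], 0)
  expect_equal(st$start_h[-1],
               (st$start_h + st$duration_h)[-nrow(st)], tolerance = 1e-9)
  # each step concentration within the profile range over its interval
  for (i in seq_len(nrow(st))) {
    t0 <- st$start_h[i]; t1 <- t0 + st$duration_h[i]
    tt <- seq(t0, t1, length.out = 50)
    cc <- approx(obsTimes(s), concentrations(s), xout = tt)$y
    expect_gte(st$AZD0156[i], min(cc) - 1e-6)
    expect_lte(st$AZD0156[i], max(cc) + 1e-6)
  }
  m <- exposureMetrics(oneDayTimeline(sch, "AZD0156"), "AZD0156",
                       reference = s)
  ref_auc <- exposureMetrics(s)$AUC
  expect_lt(abs(m$AUC - ref_auc) / ref_auc, 0.01)
})

test_that("a constant profile is represented exactly with zero mismatch", {
  const <- concentrationSeries(seq(0, 24, 0.5), rep(10, 49))
  sch <- buildExposureSchedule(const, boundaries = c(0, 3, 7, 15, 24))
  expect_true(all(steps(sch)$drug == 10))
  m <- exposureMetrics(oneDayTimeline(sch, "drug"), "drug",
                       reference = const)
  expect_equal(m$mismatch, 0, tolerance = 1e-9)
})

test_that("mismatch decreases with step count on a monotone profile", {
  s <- expDecaySeries(ke = 0.15)
  mm <- vapply(1:16, function(n) {
    sch <- buildExposureSchedule(s, nSteps = n)
    exposureMetrics(oneDayTimeline(sch, "drug"), "drug",
                    reference = s)$mismatch
  }, numeric(1))
  expect_true(all(diff(mm) <= 1e-9))
})

test_that("the Cmax-anchored policy reproduces the published reservoir tops", {
  series <- lapply(referenceSeries(), prependZero)
  sch <- buildExposureSchedule(series, boundaries = referenceBoundaries(),
                               peakPolicy = "cmax")
  expect_equal(max(steps(sch)$SN38), 5.5)
  expect_equal(max(steps(sch)$AZD0156), 192)
})

test_that("treatment timelines place schedules on the dosed days only", {
  schedules <- referenceEqualAucSchedules()
  tl <- composeTreatmentTimeline(regimenFromToken("mono"), schedules)
  hrs <- seq(0, 167.9, by = 0.25)
  sn <- timelineConcentration(tl, "SN38", hrs)
  az <- timelineConcentration(tl, "AZD0156", hrs)
  expect_true(all(sn[hrs >= 24] == 0))
  expect_true(any(sn[hrs < 24] > 0))
  expect_true(all(az == 0))

  tl77 <- composeTreatmentTimeline(regimenFromToken("combo_7_7"), schedules)
  az77 <- timelineConcentration(tl77, "AZD0156", seq(0, 167, by = 1) + 0.5)
  expect_true(all(az77 > 0))

  tl24 <- composeTreatmentTimeline(regimenFromToken("combo_gap24"), schedules)
  az24 <- timelineConcentration(tl24, "AZD0156", hrs)
  expect_true(all(az24[hrs < 24] == 0))
  expect_true(any(az24[hrs >= 24 & hrs < 96] > 0))
  expect_true(all(az24[hrs >= 96] == 0))

  tl72 <- composeTreatmentTimeline(regimenFromToken("combo_gap72"), schedules)
  az72 <- timelineConcentration(tl72, "AZD0156", hrs)
  expect_true(all(az72[hrs < 72] == 0))
  expect_true(any(az72[hrs >= 72 & hrs < 144] > 0))

  none <- composeTreatmentTimeline(
    treatmentRegimen(data.frame(analyte = character(), day = integer(),
                                mode = character())), schedules)
  expect_true(all(none@conc == 0))
})

test_that("regimen validation rejects bad tokens and double dosing", {
  expect_error(regimenFromToken("weekly"), "valid tokens")
  expect_error(treatmentRegimen(data.frame(analyte = "SN38", day = c(1, 1),
                                           mode = "pk_mimic")),
               "repeated dosing")
  expect_error(treatmentRegimen(data.frame(analyte = "SN38", day = 9,
                                           mode = "pk_mimic")),
               "within")
})

test_that("exposure metrics: rectangle AUC, self mismatch, time above", {
  stat <- staticTimeline(c(SN38 = 5.5), days = 6)
  m <- exposureMetrics(stat)
  expect_equal(m$AUC, 5.5 * 144)
  expect_equal(m$Cmax, 5.5)

  s <- referenceSeries("AZD0156")
  self <- exposureMetrics(s, reference = s)
  expect_equal(self$mismatch, 0, tolerance = 1e-9)
  expect_equal(self$Tmax, 2)  # earliest attainment of the maximum

  lin <- concentrationSeries(0:10, seq(10, 0, -1))
  m2 <- exposureMetrics(lin, threshold = 5)
  expect_equal(m2$timeAbove, 5, tolerance = 1e-9)
  expect_error(exposureMetrics(lin, threshold = -1), ">= 0")
})

test_that("pump programs have one record per reservoir switch and round-trip", {
  s <- prependZero(referenceSeries("SN38"))
  sch <- buildExposureSchedule(s, nSteps = 8)
  reg <- treatmentRegimen(data.frame(analyte = "SN38", day = 1,
                                     mode = "pk_mimic"))
  recs <- writePumpProgram(sch, reg)
  expect_equal(nrow(recs), 8)
  expect_true(all(recs$flow_uL_min == 20))

  f <- tempfile(fileext = ".csv")
  writePumpProgram(sch, reg, f)
  back <- readPumpProgram(f)
  expect_equal(back, recs, tolerance = 1e-12)

  fj <- tempfile(fileext = ".json")
  writePumpProgram(sch, reg, fj, format = "json")
  backj <- readPumpProgram(fj, format = "json")
  expect_equal(backj, recs, tolerance = 1e-12)

  # malformed record reported with its line number
  lines <- readLines(f)
  lines[4] <- paste0(lines[4], ",extra")
  writeLines(lines, f)
  expect_error(readPumpProgram(f), "line 4")
})
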