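test_that("drug-free growth matches the exponential closed form", {
  pd <- defaultPDParams()
  tr <- simulateGrowth(pd, staticTimeline(c(SN38 = 0), 7), horizon = 7)
  expected <- pd$V0 * exp(pd$kg * tr@times)
  expect_lt(max(abs(tr@volumes - expected) / expected), 1e-8)
  expect_true(all(tr@damage == 0))
})

test_that("alpha = 0 decouples the combination from the ATMi timeline", {
  schedules <- referenceEqualAucSchedules()
  pd <- defaultPDParams()
  pd$alpha <- 0
  mono <- simulateGrowth(pd, composeTreatmentTimeline(
    regimenFromToken("mono"), schedules), horizon = 7)
  combo <- simulateGrowth(pd, composeTreatmentTimeline(
    regimenFromToken("combo_7_7"), schedules), horizon = 7)
  expect_identical(mono@volumes, combo@volumes)
})

test_that("calibrated defaults reproduce the observed schedule ranking", {
  schedules <- referenceEqualAucSchedules()
  pan <- simulateRegimenPanel(defaultPDParams(), schedules)
  rv <- setNames(pan$relative_volume_pct, pan$token)
  expect_true(all(rv < 100))  # every schedule inhibits growth
  expect_true(rv["mono"] > rv["combo_gap72"])
  expect_true(rv["combo_gap72"] > rv["combo_gap24"])
  expect_true(rv["combo_gap24"] > rv["combo_1_7"])
  expect_true(rv["combo_1_7"] > rv["combo_7_7"])
  # gap monotonicity on the %GI scale
  gi <- setNames(pan$percent_gi, pan$token)
  expect_gte(gi["combo_gap24"], gi["combo_gap72"])
  expect_gte(gi["combo_gap72"], gi["mono"])
})

test_that("increasing alpha never increases the day-7 volume", {
  schedules <- referenceEqualAucSchedules()
  for (tok in c("combo_7_7", "combo_gap24")) {
    tl <- composeTreatmentTimeline(regimenFromToken(tok), schedules)
    vols <- vapply(c(0, 0.5, 1.35, 3), function(a) {
      pd <- defaultPDParams(); pd$alpha <- a
      tr <- simulateGrowth(pd, tl, horizon = 7, dt = 0.02)
      tr@volumes[length(tr@volumes)]
    }, numeric(1))
    expect_true(all(diff(vols) <= 1e-12))
  }
})

test_that("noise-free simulation is bitwise reproducible", {
  schedules <- referenceEqualAucSchedules()
  tl <- composeTreatmentTimeline(regimenFromToken("combo_gap24"), schedules)
  a <- simulateGrowth(defaultPDParams(), tl, horizon = 7)
  b <- simulateGrowth(defaultPDParams(), tl, horizon = 7)
  expect_identical(a@volumes, b@volumes)
  # observation noise is seeded and reproducible too
  n1 <- observeVolumes(a, 0.1, seed = 5)
  n2 <- observeVolumes(b, 0.1, seed = 5)
  expect_identical(n1@volumes, n2@volumes)
  expect_false(identical(n1@volumes, a@volumes))
})

test_that("percent growth inhibition has the documented fixed points", {
  ctrl <- c(1, 3)
  expect_equal(percentGrowthInhibition(ctrl, ctrl), 0)      # no effect
  expect_equal(percentGrowthInhibition(c(1, 1), ctrl), 100) # stasis
  # invariant under volume unit rescaling
  expect_equal(percentGrowthInhibition(c(2, 4), c(2, 8)),
               percentGrowthInhibition(c(2, 4) * 1e6, c(2, 8) * 1e6))
  expect_error(percentGrowthInhibition(c(1, 2), c(3, 2)), "undefined")
})

test_that("published gap-schedule %GI differences are 18 and 23 points", {
  diffs <- giGapDifference()
  expect_equal(unname(diffs["invitro_chip"]), 18)
  expect_equal(unname(diffs["invivo_xenograft"]), 23)
})

test_that("relative volume is a percent of the control mean", {
  expect_equal(relativeVolume(c(2, 1), c(2, 2, 2)), c(100, 50))
  expect_error(relativeVolume(numeric(0), 1), "empty")
  expect_error(relativeVolume(1, c(0, 0)), "> 0")
})

test_that("negative concentrations are rejected by the simulator", {
  tl <- staticTimeline(c(SN38 = 1), 7)
  m <- tl@conc; m[1, 1] <- -1
  slot(tl, "conc", check = FALSE) <- m
  expect_error(simulateGrowth(defaultPDParams(), tl, horizon = 7),
               "negative")
})
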