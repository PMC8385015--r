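# One standard synthetic spheroid shared across quantification tests.
stdImage <- generateSyntheticSpheroid(radiusUm = 150, pixelSize = 1,
                                      nCells = 250, seed = 7)

test_that("the generator is deterministic and honours its contract", {
  again <- generateSyntheticSpheroid(radiusUm = 150, pixelSize = 1,
                                     nCells = 250, seed = 7)
  expect_identical(stdImage@channels, again@channels)
  expect_identical(groundTruth(stdImage)$centroids,
                   groundTruth(again)$centroids)

  gt <- groundTruth(stdImage)
  # rasterized disc area close to the analytic value
  expect_lt(abs(sum(gt$mask) - pi * 150^2) / (pi * 150^2), 0.02)

  # zero positive fraction leaves only background in the marker channel
  blank <- generateSyntheticSpheroid(radiusUm = 80, nCells = 40, seed = 3,
                                     positiveFractions = c(gammaH2AX = 0),
                                     noiseSd = 0.01)
  expect_lt(max(getChannel(blank, "gammaH2AX")), 0.1)

  # infeasible packing rejected
  expect_error(generateSyntheticSpheroid(radiusUm = 30, nCells = 500),
               "infeasible")
})

test_that("segmentation recovers the true mask and rejects blank images", {
  mask <- segmentSpheroid(stdImage)
  gt <- groundTruth(stdImage)$mask
  iou <- sum(mask & gt) / sum(mask | gt)
  expect_gte(iou, 0.97)
  expect_error(segmentSpheroid(matrix(0.5, 50, 50)), "no spheroid")
})

test_that("mask area is robust to added noise at 5% of dynamic range", {
  bf <- getChannel(stdImage, "brightfield")
  base_area <- sum(segmentSpheroid(bf))
  set.seed(99)
  noisy <- pmax(bf + matrix(rnorm(length(bf), 0, 0.05 * diff(range(bf))),
                            nrow(bf)), 0)
  noisy_area <- sum(segmentSpheroid(noisy))
  expect_lt(abs(noisy_area - base_area) / base_area, 0.01)
})

test_that("Feret diameters recover analytic disc and ellipse extents", {
  disc <- ellipseMask(100)
  f <- feretDiameters(disc, 1)
  expect_lt(abs(f[["feret_min"]] - 200) / 200, 0.02)
  expect_lt(abs(f[["feret_max"]] - 200) / 200, 0.02)

  ell <- ellipseMask(100, 50)
  fe <- feretDiameters(ell, 1)
  expect_lt(abs(fe[["feret_max"]] - 200) / 200, 0.02)
  expect_lt(abs(fe[["feret_min"]] - 100) / 100, 0.02)

  rot <- ellipseMask(100, 50, thetaDeg = 37)
  fr <- feretDiameters(rot, 1)
  expect_lt(abs(fr[["feret_max"]] - fe[["feret_max"]]) / 200, 0.02)
  expect_lt(abs(fr[["feret_min"]] - fe[["feret_min"]]) / 100, 0.02)

  expect_error(feretDiameters(matrix(c(TRUE, rep(FALSE, 8)), 3), 1),
               "fewer than 2")
})

test_that("feret_min never exceeds feret_max on random blobs", {
  set.seed(4)
  for (i in 1:10) {
    m <- ellipseMask(sample(20:80, 1), sample(10:60, 1),
                     thetaDeg = runif(1, 0, 180))
    f <- feretDiameters(m, 1)
    expect_lte(f[["feret_min"]], f[["feret_max"]] + 1e-9)
  }
})

test_that("volume follows the average-radius sphere formula", {
  v <- spheroidVolume(200, 200)
  expect_equal(v$average_radius, 100)
  expect_equal(v$volume, 4 / 3 * pi * 1e6)
  expect_equal(spheroidVolume(200, 100 * 2)$volume,
               spheroidVolume(100, 100)$volume * 8)  # scaling law
  expect_equal(spheroidVolume(100, 200)$average_radius, 75)
  expect_equal(spheroidVolume(100, 200)$volume, 4 / 3 * pi * 75^3)
  expect_error(spheroidVolume(0, 10), "> 0")
  expect_error(spheroidVolume(30, 10), "feret_min")
})

test_that("the volume pipeline recovers analytic sphere volumes across radii", {
  for (r in c(50, 100, 150, 200)) {
    f <- feretDiameters(ellipseMask(r), 1)
    v <- spheroidVolume(f[["feret_min"]], f[["feret_max"]])$volume
    expect_lt(abs(v - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.05)
  }
})

test_that("nuclei detection hits >= 0.9 recall and precision on ground truth", {
  gt <- groundTruth(stdImage)
  mask <- segmentSpheroid(stdImage)
  cent <- detectNuclei(stdImage, mask = mask)
  m <- matchCentroids(cent, gt$centroids, radius = gt$nucleusRadius_um)
  expect_gte(m[["recall"]], 0.9)
  expect_gte(m[["precision"]], 0.9)

  # zero-signal channel yields no centroids
  zero <- matrix(0, 64, 64)
  zmask <- matrix(TRUE, 64, 64)
  expect_equal(nrow(detectNuclei(zero, mask = zmask)), 0)
})

test_that("nucleus counts are stable across seeds at fixed parameters", {
  other <- generateSyntheticSpheroid(radiusUm = 150, pixelSize = 1,
                                     nCells = 250, seed = 8)
  n1 <- nrow(detectNuclei(stdImage, mask = segmentSpheroid(stdImage)))
  n2 <- nrow(detectNuclei(other, mask = segmentSpheroid(other)))
  expect_lt(abs(n1 - n2) / n1, 0.05)
})

test_that("marker counting recovers the seeded Ki67 fraction within 0.05", {
  img <- generateSyntheticSpheroid(radiusUm = 150, nCells = 300, seed = 21,
                                   positiveFractions = c(Ki67 = 0.3))
  mask <- segmentSpheroid(img)
  cent <- detectNuclei(img, mask = mask)
  cp <- countPositive(cent, img, mask, channel = "Ki67")
  expect_lte(cp$n_positive, cp$n_nuclei)
  expect_lt(abs(cp$fraction - 0.3), 0.05)

  # all-background marker channel: zero positives, defined zero densities
  blank <- countPositive(cent, matrix(0.02, nrow(mask), ncol(mask)), mask,
                         pixelSize = 1)
  expect_equal(blank$n_positive, 0L)
  expect_equal(blank$density_per_1e4um2, 0)
  empty <- countPositive(cent[0, , drop = FALSE], img, mask,
                         channel = "Ki67")
  expect_equal(empty$n_nuclei, 0L)
  expect_equal(empty$fraction, 0)
})

test_that("a 5:1 true density ratio reads out as a ~400% increase", {
  imgHigh <- generateSyntheticSpheroid(radiusUm = 150, nCells = 300,
                                       seed = 31,
                                       positiveFractions = c(gammaH2AX = 0.5))
  imgLow <- generateSyntheticSpheroid(radiusUm = 150, nCells = 300,
                                      seed = 32,
                                      positiveFractions = c(gammaH2AX = 0.1))
  dens <- vapply(list(imgHigh, imgLow), function(im) {
    mask <- segmentSpheroid(im)
    cent <- detectNuclei(im, mask = mask)
    countPositive(cent, im, mask, channel = "gammaH2AX")$density_per_1e4um2
  }, numeric(1))
  pct_change <- 100 * (dens[1] - dens[2]) / dens[2]
  expect_lt(abs(pct_change - 400) / 400, 0.15)
})

test_that("densities scale inversely with spheroid area at fixed positives", {
  mask_small <- ellipseMask(60)
  mask_big <- ellipseMask(120)
  cent <- cbind(x = c(120, 130, 140), y = c(120, 130, 140))
  marker <- matrix(0.02, nrow(mask_big), ncol(mask_big))
  marker[cbind(c(121, 131, 141), c(121, 131, 141))] <- 50  # bright single px
  # pad the small mask into the big frame for comparable geometry
  pad <- matrix(FALSE, nrow(mask_big), ncol(mask_big))
  off <- (nrow(mask_big) - nrow(mask_small)) %/% 2
  pad[off + seq_len(nrow(mask_small)), off + seq_len(ncol(mask_small))] <-
    mask_small
  d_small <- countPositive(cent, marker, pad, pixelSize = 1)
  d_big <- countPositive(cent, marker, mask_big, pixelSize = 1)
  expect_equal(d_small$n_positive, d_big$n_positive)
  expect_gt(d_small$density_per_1e4um2, d_big$density_per_1e4um2)
  expect_equal(d_small$density_per_1e4um2 / d_big$density_per_1e4um2,
               d_big$area_um2 / d_small$area_um2, tolerance = 1e-9)
})

test_that("full quantification runs end to end and round-trips via TIFF", {
  row <- analyzeSpheroid(stdImage)
  expect_named(row, c("id", "area_um2", "feret_min", "feret_max", "radius",
                      "volume", "n_nuclei", "gh2ax_density", "cc3_density",
                      "ki67_fraction"))
  expect_gt(row$n_nuclei, 0)
  expect_true(row$feret_min <= row$feret_max)
  expect_equal(row$volume, 4 / 3 * pi * row$radius^3)

  f <- tempfile(fileext = ".tif")
  writeSpheroidTiff(stdImage, f)
  back <- readSpheroidTiff(f, channels = channelNames(stdImage),
                           pixelSize = pixelSize(stdImage))
  expect_identical(channelNames(back), channelNames(stdImage))
  # 16-bit storage: same mask recovered after the round trip
  m1 <- segmentSpheroid(stdImage)
  m2 <- segmentSpheroid(back)
  expect_gte(sum(m1 & m2) / sum(m1 | m2), 0.99)
})
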