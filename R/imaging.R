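# Spheroid image quantification: brightfield segmentation, Feret-diameter
# volumetry, nuclei detection and biomarker-positive cell counting, plus a
# seeded synthetic image generator providing ground truth for benchmarking.
#
# Pixel conventions: coordinates are 0-based (x = column, y = row), matrices
# are indexed [row, col], areas are pixel counts times pixelSize^2, connected
# components use 8-connectivity.

# evaluate expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# integer pixel offsets of a disc of radius r (pixels)
.disc_offsets <- function(r) {
  s <- seq(-ceiling(r), ceiling(r))
  g <- expand.grid(dy = s, dx = s)
  g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
}

# add a Gaussian spot kernel (amplitude amp, sd in px) at each centre
.render_spots <- function(dim, centres, sd_px, amp = 1) {
  img <- matrix(0, dim[1], dim[2])
  if (!nrow(centres)) return(img)
  half <- ceiling(3 * sd_px)
  ax <- seq(-half, half)
  k <- exp(-outer(ax^2, ax^2, "+") / (2 * sd_px^2)) * amp
  n <- 2 * half + 1
  for (i in seq_len(nrow(centres))) {
    r0 <- round(centres[i, 2]) + 1  # y -> row (1-based)
    c0 <- round(centres[i, 1]) + 1
    rr <- (r0 - half):(r0 + half)
    cc <- (c0 - half):(c0 + half)
    okr <- rr >= 1 & rr <= dim[1]; okc <- cc >= 1 & cc <= dim[2]
    img[rr[okr], cc[okc]] <- img[rr[okr], cc[okc]] +
      k[seq_len(n)[okr], seq_len(n)[okc]]
  }
  img
}

#' Generate a synthetic spheroid image with ground truth
#'
#' Renders a roughly circular (optionally elliptical) spheroid as a dark
#' disc on a bright brightfield background, packs nuclei inside it by seeded
#' Poisson-disc (dart-throwing) sampling rendered as Gaussian spots in the
#' nuclei channel, and lights a seeded random subset of nuclei in each
#' marker channel at the requested positive fraction. Ground truth (mask,
#' centroids, positive labels) is recorded for benchmarking. Regeneration at
#' a fixed seed is bitwise identical; the global RNG state is restored.
#'
#' @param radiusUm spheroid semi-major axis, microns (default 150, matching
#'   the 250-370 um diameter of day-0/1 spheroids on the platform).
#' @param pixelSize microns per pixel (default 1).
#' @param nCells number of nuclei to place.
#' @param positiveFractions named vector of per-marker positive fractions in
#'   `[0, 1]`; channel per name (default gammaH2AX, CC3, Ki67).
#' @param noiseSd additive Gaussian background noise SD, in intensity units
#'   where a nucleus spot has amplitude 1.
#' @param seed integer seed.
#' @param aspect minor/major axis ratio (1 = disc).
#' @param thetaDeg ellipse rotation, degrees.
#' @param nucleusRadiusUm nucleus radius, microns (default 4).
#' @param minSpacingUm minimum nucleus centre spacing, microns (default
#'   `2.2 * nucleusRadiusUm`).
#' @param pad background margin around the spheroid, microns.
#' @return a [SpheroidImage-class] with channels `brightfield`, `nuclei` and
#'   one per marker, plus ground truth.
#' @export
generateSyntheticSpheroid <- function(radiusUm = 150, pixelSize = 1,
                                      nCells = 250,
                                      positiveFractions = c(gammaH2AX = 0.2,
                                                            CC3 = 0.1,
                                                            Ki67 = 0.4),
                                      noiseSd = 0.02, seed = 1, aspect = 1,
                                      thetaDeg = 0, nucleusRadiusUm = 4,
                                      minSpacingUm = 2.2 * nucleusRadiusUm,
                                      pad = 40) {
  if (!isTRUE(radiusUm > 0)) stop("radiusUm must be > 0")
  if (any(positiveFractions < 0 | positiveFractions > 1))
    stop("positive fractions must lie in [0, 1]")
  ps <- pixelSize
  a_px <- radiusUm / ps
  b_px <- a_px * aspect
  half <- ceiling(a_px + pad / ps)
  dimpx <- c(2 * half + 1, 2 * half + 1)  # rows, cols
  cx <- half; cy <- half                  # centre, 0-based

  # elliptical mask
  th <- thetaDeg * pi / 180
  col0 <- matrix(rep(0:(dimpx[2] - 1), each = dimpx[1]), dimpx[1])
  row0 <- matrix(rep(0:(dimpx[1] - 1), times = dimpx[2]), dimpx[1])
  xr <- (col0 - cx) * cos(th) + (row0 - cy) * sin(th)
  yr <- -(col0 - cx) * sin(th) + (row0 - cy) * cos(th)
  mask <- (xr / a_px)^2 + (yr / b_px)^2 <= 1

  # feasibility: packing bound for dart throwing
  area_px <- sum(mask)
  spacing_px <- minSpacingUm / ps
  if (nCells > 0.7 * area_px / (pi * (spacing_px / 2)^2))
    stop("n_cells infeasible for the spheroid area at the minimum spacing")

  .with_seed(seed, {
    # Poisson-disc by dart throwing inside the mask, eroded by one nucleus
    # radius so spots stay inside the spheroid
    nr_px <- nucleusRadiusUm / ps
    centres <- matrix(numeric(0), 0, 2)
    tries <- 0L; max_tries <- 400L * nCells
    inner <- function(x, y) {
      xr <- (x - cx) * cos(th) + (y - cy) * sin(th)
      yr <- -(x - cx) * sin(th) + (y - cy) * cos(th)
      (xr / (a_px - nr_px))^2 + (yr / max(b_px - nr_px, 1))^2 <= 1
    }
    while (nrow(centres) < nCells && tries < max_tries) {
      tries <- tries + 1L
      x <- runif(1, 0, dimpx[2] - 1); y <- runif(1, 0, dimpx[1] - 1)
      if (!inner(x, y)) next
      if (nrow(centres) &&
          min((centres[, 1] - x)^2 + (centres[, 2] - y)^2) < spacing_px^2)
        next
      centres <- rbind(centres, c(x, y))
    }
    if (nrow(centres) < nCells)
      stop("n_cells infeasible for the spheroid area at the minimum spacing")
    colnames(centres) <- c("x", "y")

    spot_sd <- nr_px / 2
    nuclei <- .render_spots(dimpx, centres, spot_sd) +
      matrix(rnorm(prod(dimpx), 0.02, noiseSd), dimpx[1])
    nuclei <- pmax(nuclei, 0)

    channels <- list()
    bf <- matrix(0.85, dimpx[1], dimpx[2])
    bf[mask] <- 0.35
    bf <- as.matrix(EBImage::gblur(EBImage::Image(bf), sigma = 1.5)) +
      matrix(rnorm(prod(dimpx), 0, noiseSd), dimpx[1])
    channels$brightfield <- pmax(bf, 0)
    channels$nuclei <- nuclei

    positive <- list()
    for (m in names(positiveFractions)) {
      npos <- round(positiveFractions[[m]] * nCells)
      lab <- logical(nCells)
      if (npos > 0) lab[sample.int(nCells, npos)] <- TRUE
      positive[[m]] <- lab
      ch <- .render_spots(dimpx, centres[lab, , drop = FALSE], spot_sd) +
        matrix(rnorm(prod(dimpx), 0.02, noiseSd), dimpx[1])
      channels[[m]] <- pmax(ch, 0)
    }

    new("SpheroidImage", channels = channels, pixelSize = ps,
        groundTruth = list(mask = mask, centroids = centres,
                           positive = positive, radius_um = radiusUm,
                           aspect = aspect, thetaDeg = thetaDeg,
                           nucleusRadius_um = nucleusRadiusUm))
  })
}

#' Segment the spheroid from a brightfield channel
#'
#' Gaussian smoothing, global Otsu threshold (spheroid darker than
#' background), largest 8-connected component, hole filling.
#'
#' @param x a [SpheroidImage-class] or a numeric matrix (brightfield).
#' @param channel channel name when `x` is a `SpheroidImage`.
#' @param smoothSigma smoothing SD in pixels.
#' @return logical matrix mask.
#' @export
segmentSpheroid <- function(x, channel = "brightfield", smoothSigma = 2) {
  bf <- if (is(x, "SpheroidImage")) getChannel(x, channel) else x
  if (!length(bf)) stop("empty channel")
  rng <- range(bf)
  if (diff(rng) <= 0) stop("no spheroid detected (uniform image)")
  norm <- (bf - rng[1]) / diff(rng)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(norm), sigma = smoothSigma))
  sm <- pmin(pmax(sm, 0), 1)
  thr <- EBImage::otsu(EBImage::Image(sm))
  fg <- sm < thr  # dark object on bright background
  if (!any(fg)) stop("no spheroid detected")
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  tab <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  biggest <- which.max(tab)
  keep <- matrix(as.integer(lab) == biggest, nrow(bf))
  filled <- EBImage::fillHull(EBImage::Image(keep * 1))
  as.matrix(filled) > 0.5
}

#' Minimum and maximum Feret (caliper) diameters of a mask
#'
#' Rotating-projection extents of the convex hull of the mask pixels at 1
#' degree angular resolution; one pixel is added to each extent to account
#' for pixel width, and the result is scaled to microns.
#'
#' @param mask logical matrix (from [segmentSpheroid()] or ground truth).
#' @param pixelSize microns per pixel.
#' @param angularStepDeg angular resolution, degrees (default 1).
#' @return named numeric `c(feret_min, feret_max)` in microns.
#' @export
feretDiameters <- function(mask, pixelSize = 1, angularStepDeg = 1) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2) stop("mask has fewer than 2 pixels")
  pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  ang <- seq(0, 180 - angularStepDeg, by = angularStepDeg) * pi / 180
  proj <- hull %*% rbind(cos(ang), sin(ang))
  ext <- apply(proj, 2, function(p) max(p) - min(p)) + 1
  c(feret_min = min(ext), feret_max = max(ext)) * pixelSize
}

#' Spheroid volume from min/max Feret diameters
#'
#' The average radius is taken as `(feret_min + feret_max) / 4` (mean of the
#' two caliper diameters, halved) and the volume as that of the sphere with
#' this radius: `(4/3) * pi * r^3`.
#'
#' @param feretMin,feretMax Feret diameters, microns, `0 < min <= max`.
#' @return list with `average_radius` (um) and `volume` (um^3).
#' @examples
#' spheroidVolume(200, 200)$volume  # (4/3)*pi*1e6
#' @export
spheroidVolume <- function(feretMin, feretMax) {
  if (!isTRUE(feretMin > 0) || !isTRUE(feretMax > 0))
    stop("Feret diameters must be > 0")
  if (feretMin > feretMax) stop("require feret_min <= feret_max")
  r <- (feretMin + feretMax) / 4
  list(average_radius = r, volume = 4 / 3 * pi * r^3)
}

#' Area, Feret diameters, radius and volume of one spheroid
#'
#' Runs segmentation ([segmentSpheroid()]), Feret extraction
#' ([feretDiameters()]) and volumetry ([spheroidVolume()]).
#'
#' @param image a [SpheroidImage-class].
#' @param mask optional precomputed mask.
#' @param id identifier for the output row.
#' @return one-row data.frame: `id`, `area_um2`, `feret_min`, `feret_max`,
#'   `radius`, `volume`.
#' @export
measureSpheroid <- function(image, mask = NULL, id = "spheroid") {
  if (is.null(mask)) mask <- segmentSpheroid(image)
  ps <- pixelSize(image)
  fer <- feretDiameters(mask, ps)
  vol <- spheroidVolume(fer[["feret_min"]], fer[["feret_max"]])
  data.frame(id = id, area_um2 = sum(mask) * ps^2,
             feret_min = fer[["feret_min"]], feret_max = fer[["feret_max"]],
             radius = vol$average_radius, volume = vol$volume,
             stringsAsFactors = FALSE)
}

#' Detect nuclei as local maxima in the nuclei channel
#'
#' Background-subtracted Gaussian smoothing followed by local-maximum
#' detection at a minimum separation of twice the expected nucleus radius,
#' restricted to the spheroid mask. A maximum must exceed the background
#' level (outside-mask mean + 3 SD) to count.
#'
#' @param image a [SpheroidImage-class] (or numeric matrix).
#' @param mask spheroid mask; defaults to [segmentSpheroid()] on the image.
#' @param channel nuclei channel name.
#' @param nucleusRadiusUm expected nucleus radius, microns.
#' @return matrix with columns `x`, `y` (0-based pixel coordinates).
#' @export
detectNuclei <- function(image, mask = NULL, channel = "nuclei",
                         nucleusRadiusUm = 4) {
  ch <- if (is(image, "SpheroidImage")) getChannel(image, channel) else image
  ps <- if (is(image, "SpheroidImage")) pixelSize(image) else 1
  if (is.null(mask)) mask <- segmentSpheroid(image)
  r_px <- nucleusRadiusUm / ps
  sm <- as.matrix(EBImage::gblur(EBImage::Image(ch), sigma = r_px / 2))
  bgvals <- sm[!mask]
  thr <- if (length(bgvals)) mean(bgvals) + 3 * stats::sd(bgvals) else 0
  sep_px <- max(1, round(2 * r_px))
  bsize <- 2 * sep_px + 1
  brush <- EBImage::makeBrush(bsize, shape = "disc")
  dil <- as.matrix(EBImage::dilate(EBImage::Image(sm), brush))
  is_max <- sm >= dil - 1e-12 & sm > thr & mask
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(matrix(numeric(0), 0, 2,
                                dimnames = list(NULL, c("x", "y"))))
  # merge plateau maxima closer than the separation
  pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  ord <- order(-sm[idx])
  pts <- pts[ord, , drop = FALSE]
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (!nrow(kept) ||
        min((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2) >= sep_px^2)
      kept <- rbind(kept, p)
  }
  colnames(kept) <- c("x", "y")
  rownames(kept) <- NULL
  kept
}

#' Count biomarker-positive nuclei with area normalisation
#'
#' A nucleus is positive for a marker when its mean intensity within a disc
#' of one nucleus radius exceeds the background mean + `k` SD, where the
#' background is the image outside the dilated spheroid mask. DNA-damage and
#' apoptosis markers are reported as positives per 10^4 um^2 of spheroid
#' area; proliferation markers (Ki67) as a fraction of all nuclei, which
#' needs no area normalisation.
#'
#' @param centroids matrix from [detectNuclei()].
#' @param marker marker channel (numeric matrix) or a
#'   [SpheroidImage-class] plus `channel`.
#' @param mask spheroid mask.
#' @param pixelSize microns per pixel (taken from the image if supplied).
#' @param channel marker channel name when `marker` is a `SpheroidImage`.
#' @param nucleusRadiusUm nucleus radius, microns.
#' @param k positivity threshold in background SD units (default 3).
#' @return list with `n_nuclei`, `n_positive`, `area_um2`,
#'   `density_per_1e4um2`, `fraction`.
#' @export
countPositive <- function(centroids, marker, mask, pixelSize = 1,
                          channel = NULL, nucleusRadiusUm = 4, k = 3) {
  if (is(marker, "SpheroidImage")) {
    pixelSize <- pixelSize(marker)
    marker <- getChannel(marker, channel)
  }
  area <- sum(mask) * pixelSize^2
  n <- nrow(centroids)
  if (n == 0)
    return(list(n_nuclei = 0L, n_positive = 0L, area_um2 = area,
                density_per_1e4um2 = 0, fraction = 0))
  r_px <- nucleusRadiusUm / pixelSize
  big <- EBImage::makeBrush(2 * ceiling(2 * r_px) + 1, shape = "disc")
  bg_region <- !(as.matrix(EBImage::dilate(EBImage::Image(mask * 1), big)) > 0.5)
  bgvals <- marker[bg_region]
  thr <- mean(bgvals) + k * stats::sd(bgvals)
  offs <- .disc_offsets(r_px)
  nr <- nrow(marker); nc <- ncol(marker)
  pos <- logical(n)
  for (i in seq_len(n)) {
    rr <- round(centroids[i, 2]) + 1 + offs$dy
    cc <- round(centroids[i, 1]) + 1 + offs$dx
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    pos[i] <- mean(marker[cbind(rr[ok], cc[ok])]) > thr
  }
  np <- sum(pos)
  list(n_nuclei = n, n_positive = np, area_um2 = area,
       density_per_1e4um2 = np / area * 1e4, fraction = np / n)
}

#' Full quantification of one spheroid image
#'
#' Segmentation, volumetry, nuclei detection and positive-cell counting for
#' the standard marker panel.
#'
#' @param image a [SpheroidImage-class] with `brightfield`, `nuclei` and
#'   marker channels.
#' @param markers marker channel names to count (those present are used).
#' @param id identifier for the output row.
#' @param nucleusRadiusUm nucleus radius, microns.
#' @return one-row data.frame: `id`, `area_um2`, `feret_min`, `feret_max`,
#'   `radius`, `volume`, `n_nuclei`, `gh2ax_density`, `cc3_density`,
#'   `ki67_fraction` (NA for absent channels).
#' @export
analyzeSpheroid <- function(image, markers = c("gammaH2AX", "CC3", "Ki67"),
                            id = "spheroid", nucleusRadiusUm = 4) {
  mask <- segmentSpheroid(image)
  meas <- measureSpheroid(image, mask = mask, id = id)
  cent <- detectNuclei(image, mask = mask, nucleusRadiusUm = nucleusRadiusUm)
  res <- list(gammaH2AX = NA_real_, CC3 = NA_real_, Ki67 = NA_real_)
  for (m in intersect(markers, channelNames(image))) {
    cp <- countPositive(cent, image, mask, channel = m,
                        nucleusRadiusUm = nucleusRadiusUm)
    res[[m]] <- if (m == "Ki67") cp$fraction else cp$density_per_1e4um2
  }
  cbind(meas, data.frame(n_nuclei = nrow(cent),
                         gh2ax_density = res$gammaH2AX,
                         cc3_density = res$CC3,
                         ki67_fraction = res$Ki67))
}

#' Write / read a multichannel spheroid image as TIFF
#'
#' Channels are stored as TIFF frames in the order of `channelNames()`;
#' channel names and pixel size are not stored in the file and must be
#' supplied on reading.
#'
#' @param image a [SpheroidImage-class].
#' @param path file path (`.tif`).
#' @param channels channel names to assign on reading.
#' @param pixelSize microns per pixel to assign on reading.
#' @return `readSpheroidTiff` returns a [SpheroidImage-class].
#' @export
writeSpheroidTiff <- function(image, path) {
  arr <- simplify2array(image@channels)
  arr <- arr / max(arr, 1)  # writeImage clips outside [0, 1]
  EBImage::writeImage(EBImage::Image(arr), path, type = "tiff",
                      bits.per.sample = 16)
  invisible(path)
}

#' @rdname writeSpheroidTiff
#' @export
readSpheroidTiff <- function(path, channels, pixelSize = 1) {
  arr <- as.array(EBImage::readImage(path))
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  if (dim(arr)[3] != length(channels))
    stop("channel name count does not match TIFF frame count")
  chs <- setNames(lapply(seq_along(channels), function(i) arr[, , i]),
                  channels)
  new("SpheroidImage", channels = chs, pixelSize = pixelSize,
      groundTruth = list())
}
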