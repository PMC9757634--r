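#' @include constructors.R
NULL

#' Sample a cell count from a decreasing truncated-geometric distribution
#'
#' Cell-count frequencies in cultivation experiments fall off towards high
#' counts, and chambers with more than 30 cells are discarded because the
#' experiment outcome is already determined.  The generator therefore draws
#' counts from a truncated geometric distribution on
#' `[minCount, maxCount]`, whose probability mass function is monotonically
#' non-increasing in the count.
#'
#' @param distributionParams list with `minCount` (default 1), `maxCount`
#'   (default 30, never above 30) and `geomP` (geometric success
#'   probability, default 0.15; larger values concentrate mass on low
#'   counts).
#' @param n number of draws.
#' @return integer vector of counts; uses the current RNG stream.
#' @examples
#' set.seed(1)
#' table(sampleCount(list(minCount = 1, maxCount = 10, geomP = 0.3), n = 100))
#' @export
sampleCount <- function(distributionParams = list(), n = 1) {
  p <- countDistributionParams(distributionParams)
  support <- p$minCount:p$maxCount
  pmf <- (1 - p$geomP)^(support - p$minCount)
  pmf <- pmf / sum(pmf)
  if (length(support) == 1L) return(rep(support, n))
  sample(support, n, replace = TRUE, prob = pmf)
}

countDistributionParams <- function(distributionParams) {
  p <- modifyList(list(minCount = 1L, maxCount = 30L, geomP = 0.15),
                  as.list(distributionParams))
  p$minCount <- as.integer(p$minCount)
  p$maxCount <- as.integer(p$maxCount)
  if (p$minCount < 0 || p$minCount > 30 || p$maxCount > 30 ||
      p$maxCount < p$minCount)
    stop("invalid count support: need 0 <= minCount <= maxCount <= 30")
  if (p$geomP <= 0 || p$geomP >= 1) stop("geomP must be in (0, 1)")
  p
}

#' Truncated-geometric probability mass function of the count distribution
#'
#' Closed form used for goodness-of-fit checks of generated label
#' histograms.
#'
#' @inheritParams sampleCount
#' @return named numeric vector of probabilities over the support.
#' @export
countPMF <- function(distributionParams = list()) {
  p <- countDistributionParams(distributionParams)
  support <- p$minCount:p$maxCount
  pmf <- (1 - p$geomP)^(support - p$minCount)
  setNames(pmf / sum(pmf), support)
}

#' Sample the generative description of one synthetic image
#'
#' Places `count` deformed-ellipse cells on the canvas.  With probability
#' `preset@overlapProbability` a new cell is deliberately dropped within
#' one cell diameter of an existing cell (emulating dividing or clumping
#' cells); otherwise its position is rejection-sampled to be disjoint from
#' all earlier cells, with at most 1000 retries before a generation error
#' (the required separation relaxes progressively during the retries, so
#' crowded scenes pack their cells into clumps instead of failing).
#' All cell attributes (semi-axes, rotation, deformation and its phases,
#' interior and rim brightness, edge blur) are drawn from the preset
#' ranges; geometric sizes scale with `resolution / 128`.  Cell centers may
#' lie within 2 px of the border, so partially visible cells occur, as in
#' real cultivation chambers.
#'
#' @param preset a [StylePreset-class].
#' @param count number of cells, 0 to 30.
#' @param resolution image side in pixels (multiple of 32).
#' @param seed optional integer stored in the scene and used for the
#'   rendering noise map.
#' @return a [SceneSpec-class] whose label is exactly `count`; uses the
#'   current RNG stream.
#' @examples
#' set.seed(42)
#' sampleScene(stylePreset("bf"), count = 5)
#' @export
sampleScene <- function(preset, count, resolution = 128L, seed = NA_integer_) {
  stopifnot(is(preset, "StylePreset"))
  if (count < 0 || count > 30) stop("count must be in [0, 30]")
  resolution <- as.integer(resolution)
  scale <- resolution / 128
  runifr <- function(r) runif(1, r[1], r[2])
  cells <- data.frame(row = numeric(0), col = numeric(0), a = numeric(0),
                      b = numeric(0), rotation = numeric(0),
                      deformation = numeric(0), phase2 = numeric(0),
                      phase3 = numeric(0), interior = numeric(0),
                      rim = numeric(0), rimw = numeric(0), blur = numeric(0))
  lo <- 2; hi <- resolution - 3
  for (i in seq_len(count)) {
    a <- runifr(preset@semiAxisRange) * scale
    b <- runifr(preset@semiAxisRange) * scale
    placed <- FALSE
    if (i > 1 && runif(1) < preset@overlapProbability) {
      j <- sample(i - 1L, 1L)
      dia <- 2 * max(cells$a[j], cells$b[j])
      ang <- runif(1, 0, 2 * pi)
      d <- runif(1, 0.3, 1) * dia
      row <- min(max(cells$row[j] + d * sin(ang), lo), hi)
      col <- min(max(cells$col[j] + d * cos(ang), lo), hi)
      placed <- TRUE
    }
    if (!placed) {
      # the required separation relaxes every 250 failed retries, so dense
      # scenes fall back to the clumped packing seen in crowded chambers
      for (try in seq_len(1000)) {
        row <- runif(1, lo, hi); col <- runif(1, lo, hi)
        if (i == 1) { placed <- TRUE; break }
        relax <- c(1, 0.75, 0.5, 0.2)[1 + (try - 1) %/% 250]
        dmin <- sqrt((cells$row - row)^2 + (cells$col - col)^2)
        sep <- (pmax(cells$a, cells$b) + max(a, b)) * relax
        if (all(dmin > sep)) { placed <- TRUE; break }
      }
      if (!placed)
        stop(sprintf("could not place %d cells on a %dx%d canvas after 1000 retries",
                     count, resolution, resolution))
    }
    rim <- if (all(is.na(preset@rimBrightnessRange))) NA_real_
           else runifr(preset@rimBrightnessRange)
    cells[i, ] <- list(row, col, a, b, runif(1, 0, 360),
                       runifr(preset@deformationRange),
                       runif(1, 0, 2 * pi), runif(1, 0, 2 * pi),
                       runifr(preset@interiorBrightnessRange), rim,
                       preset@rimWidth * scale, runifr(preset@edgeBlurRange))
  }
  new("SceneSpec", cells = cells,
      backgroundLevel = preset@backgroundLevel,
      noiseAmplitude = runifr(preset@noiseAmplitudeRange),
      style = preset@name, resolution = resolution,
      seed = as.integer(seed))
}

# Paint one cell onto the canvas: a deformed ellipse (low-order radial
# Fourier perturbation of the contour), optionally with a bright rim, alpha
# composited after a per-cell Gaussian edge blur.
paintCell <- function(canvas, cell) {
  rimWidth <- if (is.na(cell$rim)) 0 else cell$rimw
  res <- nrow(canvas)
  rmax <- max(cell$a, cell$b) * (1 + cell$deformation) + rimWidth
  pad <- ceiling(rmax + 3 * cell$blur + 1)
  r0 <- max(1L, floor(cell$row) - pad + 1L)
  r1 <- min(res, ceiling(cell$row) + pad + 1L)
  c0 <- max(1L, floor(cell$col) - pad + 1L)
  c1 <- min(res, ceiling(cell$col) + pad + 1L)
  if (r0 > r1 || c0 > c1) return(canvas)
  rows <- r0:r1; cols <- c0:c1
  y <- matrix(rows - 1 - cell$row, length(rows), length(cols))
  x <- matrix(cols - 1 - cell$col, length(rows), length(cols), byrow = TRUE)
  th <- cell$rotation * pi / 180
  u <- (x * cos(th) + y * sin(th)) / cell$a
  v <- (-x * sin(th) + y * cos(th)) / cell$b
  r <- sqrt(u^2 + v^2)
  phi <- atan2(v, u)
  rho <- 1 + cell$deformation * (0.6 * cos(2 * phi + cell$phase2) +
                                 0.4 * cos(3 * phi + cell$phase3))
  inside <- r <= rho
  V <- matrix(0, length(rows), length(cols))
  M <- matrix(0, length(rows), length(cols))
  V[inside] <- cell$interior
  M[inside] <- 1
  if (!is.na(cell$rim) && rimWidth > 0) {
    wr <- rimWidth / sqrt(cell$a * cell$b)
    rim <- !inside & r <= rho + wr
    V[rim] <- cell$rim
    M[rim] <- 1
  }
  if (cell$blur > 0.05) {
    V <- EBImage::imageData(EBImage::gblur(V, sigma = cell$blur))
    M <- EBImage::imageData(EBImage::gblur(M, sigma = cell$blur))
    M <- pmin(pmax(M, 0), 1)
  }
  patch <- canvas[rows, cols]
  canvas[rows, cols] <- patch * (1 - M) + V
  canvas
}

#' Render a scene into an image
#'
#' Deterministic rendering pipeline: paint the constant background, paint
#' each deformed ellipse (interior plus bright rim for the pc style), blur
#' each cell with its own Gaussian edge-blur sigma, add a zero-centered
#' Gaussian noise map of the scene's amplitude, and clip to `[0, 1]`.  If
#' the scene carries a seed the noise map is drawn from it (so rendering is
#' a pure function of the scene); otherwise the current RNG stream is used.
#'
#' @param scene a [SceneSpec-class].
#' @param modality modality tag of the returned sample.
#' @param id identifier of the returned sample.
#' @return an [ImageSample-class] whose label equals `nrow(scene@cells)`.
#' @examples
#' set.seed(7)
#' sc <- sampleScene(stylePreset("pc"), 3, resolution = 64)
#' img <- renderScene(sc)
#' range(img@pixels)
#' @export
renderScene <- function(scene, modality = "synthetic", id = "scene") {
  stopifnot(is(scene, "SceneSpec"))
  res <- scene@resolution
  canvas <- matrix(scene@backgroundLevel, res, res)
  for (i in seq_len(nrow(scene@cells)))
    canvas <- paintCell(canvas, scene@cells[i, ])
  addNoise <- function() {
    if (scene@noiseAmplitude > 0)
      canvas + matrix(rnorm(res * res, 0, scene@noiseAmplitude), res, res)
    else canvas
  }
  canvas <- if (!is.na(scene@seed)) withSeed(scene@seed, addNoise()) else addNoise()
  canvas <- pmin(pmax(canvas, 0), 1)
  new("ImageSample", pixels = canvas, label = nrow(scene@cells),
      modality = modality, style = scene@style, id = id)
}

#' Generate a synthetic image set in memory
#'
#' Draws `n` counts from the configured truncated-geometric distribution,
#' samples a scene for each and renders it.  Fully seeded: each image uses
#' an independent sub-stream derived from `seed`, so any subset can be
#' reproduced and the whole call is a pure function of its arguments.
#'
#' @param preset a [StylePreset-class].
#' @param n number of images.
#' @param distributionParams see [sampleCount()].
#' @param seed master seed.
#' @param resolution image side in pixels.
#' @param modality modality tag applied to all images.
#' @return an [ImageSet-class] with exact ground-truth labels.
#' @examples
#' s <- generateImageSet(stylePreset("bf"), 4, seed = 1, resolution = 64)
#' sampleLabels(s)
#' @export
generateImageSet <- function(preset, n, distributionParams = list(),
                             seed = 1, resolution = 128L,
                             modality = "synthetic") {
  stopifnot(n > 0)
  resolution <- as.integer(resolution)
  arr <- array(0, c(resolution, resolution, n))
  labels <- integer(n)
  ids <- sprintf("%s_%05d", preset@name, seq_len(n))
  for (i in seq_len(n)) {
    si <- seedStream(seed, paste0("img", i))
    smp <- withSeed(si, {
      cnt <- sampleCount(distributionParams)
      scene <- sampleScene(preset, cnt, resolution, seed = si)
      renderScene(scene, modality = modality, id = ids[i])
    })
    arr[, , i] <- smp@pixels
    labels[i] <- smp@label
  }
  new("ImageSet", images = arr, label = labels,
      modality = rep(modality, n), style = rep(preset@name, n), id = ids)
}

#' Generate a synthetic data set on disk
#'
#' Renders `n` images (see [generateImageSet()]) and writes them as 8-bit
#' grayscale PNG files plus a CSV manifest (`filename,label,modality,style`)
#' into `outDir`.  Rerunning with identical arguments reproduces the
#' directory byte for byte.
#'
#' @inheritParams generateImageSet
#' @param outDir output directory, created if missing.
#' @return a [DatasetManifest-class] (invisibly) pointing at `outDir`.
#' @export
generateDataset <- function(preset, n, distributionParams = list(),
                            seed = 1, outDir, resolution = 128L) {
  set <- generateImageSet(preset, n, distributionParams, seed, resolution)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  fns <- paste0(set@id, ".png")
  for (i in seq_len(nImages(set)))
    writeGrayPNG(set@images[, , i], file.path(outDir, fns[i]))
  manifest <- new("DatasetManifest",
                  data = data.frame(filename = fns, label = set@label,
                                    modality = set@modality,
                                    style = set@style,
                                    stringsAsFactors = FALSE),
                  root = outDir, split = "train")
  writeManifest(manifest, file.path(outDir, "manifest.csv"))
  invisible(manifest)
}

#' Estimate the synthetic background level from reference images
#'
#' The synthetic background is matched to real data by averaging all
#' pixels of the reference images that show fewer than `maxCount` cells —
#' sparse chambers are mostly background, so their mean gray level is a
#' robust background estimate.
#'
#' @param reference an [ImageSet-class] with labels.
#' @param maxCount only images with `label < maxCount` contribute.
#' @return scalar mean gray level, suitable for
#'   `stylePreset(..., backgroundLevel = )`.
#' @export
backgroundFromReference <- function(reference, maxCount = 5) {
  stopifnot(is(reference, "ImageSet"))
  keep <- !is.na(reference@label) & reference@label < maxCount
  if (!any(keep))
    stop("no reference image with label below ", maxCount)
  mean(reference@images[, , keep])
}
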