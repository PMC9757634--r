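#' @include AllClasses.R
NULL

#' Built-in style presets for the synthetic-image generator
#'
#' Returns the generator preset for one of the two emulated microscopy
#' styles.  `"bf"` renders faint cells slightly darker than a bright
#' background, as in bright-field microscopy of suspension cells; `"pc"`
#' renders dark interiors surrounded by the bright halo characteristic of
#' phase-contrast optics, on a darker background.  Any slot can be
#' overridden through `...`.
#'
#' @param name `"bf"` or `"pc"`.
#' @param ... named slot overrides, e.g. `overlapProbability = 0.3`.
#' @return a [StylePreset-class].
#' @examples
#' p <- stylePreset("pc", noiseAmplitudeRange = c(0, 0))
#' p
#' @export
stylePreset <- function(name = c("bf", "pc"), ...) {
  name <- match.arg(name)
  defaults <- if (name == "bf") {
    list(
      interiorBrightnessRange = c(0.42, 0.62),
      rimBrightnessRange = c(NA_real_, NA_real_),
      semiAxisRange = c(5, 12),
      deformationRange = c(0.02, 0.18),
      edgeBlurRange = c(0.6, 1.6),
      backgroundLevel = 0.75,
      noiseAmplitudeRange = c(0.01, 0.04),
      overlapProbability = 0.1,
      rimWidth = 0
    )
  } else {
    list(
      interiorBrightnessRange = c(0.12, 0.32),
      rimBrightnessRange = c(0.85, 1.0),
      semiAxisRange = c(5, 12),
      deformationRange = c(0.02, 0.18),
      edgeBlurRange = c(0.4, 1.2),
      backgroundLevel = 0.40,
      noiseAmplitudeRange = c(0.01, 0.05),
      overlapProbability = 0.1,
      rimWidth = 1.5
    )
  }
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad)) stop("unknown preset field(s): ", paste(bad, collapse = ", "))
  defaults[names(override)] <- override
  do.call(new, c(list("StylePreset", name = name), defaults))
}

#' Construct a single annotated image
#'
#' @param pixels square numeric matrix in `[0, 1]`.
#' @param label integer cell count or `NA`.
#' @param modality `"natural"` or `"synthetic"`.
#' @param style `"bf"` or `"pc"`.
#' @param id identifier string.
#' @return an [ImageSample-class].
#' @export
imageSample <- function(pixels, label = NA_integer_,
                        modality = c("synthetic", "natural"),
                        style = c("bf", "pc"), id = "sample") {
  new("ImageSample", pixels = pixels, label = as.integer(label),
      modality = match.arg(modality), style = match.arg(style), id = id)
}

#' Construct an image set
#'
#' @param images `H x W x n` array, or a list of [ImageSample-class]
#'   objects (in which case the other arguments are taken from them).
#' @param label integer vector (`NA` = unlabeled).
#' @param modality,style,id per-image annotation vectors (recycled).
#' @return an [ImageSet-class].
#' @export
imageSet <- function(images, label = NA_integer_, modality = "synthetic",
                     style = "bf", id = NULL) {
  if (is.list(images)) {
    samples <- images
    stopifnot(all(vapply(samples, is, TRUE, "ImageSample")))
    res <- nrow(samples[[1]]@pixels)
    arr <- array(0, c(res, res, length(samples)))
    for (i in seq_along(samples)) arr[, , i] <- samples[[i]]@pixels
    return(new("ImageSet", images = arr,
               label = vapply(samples, function(s) s@label, 1L),
               modality = vapply(samples, function(s) s@modality, ""),
               style = vapply(samples, function(s) s@style, ""),
               id = vapply(samples, function(s) s@id, "")))
  }
  n <- dim(images)[3]
  if (is.null(id)) id <- sprintf("img%05d", seq_len(n))
  new("ImageSet", images = images, label = rep(as.integer(label), length.out = n),
      modality = rep(modality, length.out = n),
      style = rep(style, length.out = n), id = rep(id, length.out = n))
}

#' Twin-loss weights for one modality
#'
#' Defaults are the phase-contrast training weights (reconstruction 100,
#' regression 3, KL 2 with mean-squared-error reconstruction); the decay
#' rate only acts when `recKind = "bce"`.
#'
#' @param cRec,cReg,cKL non-negative weights.
#' @param recKind `"mse"` or `"bce"` (pixel-wise binary cross-entropy).
#' @param recDecayRate per-epoch multiplicative decay of `cRec` under
#'   `"bce"`.
#' @return a [LossWeights-class].
#' @export
lossWeights <- function(cRec = 100, cReg = 3, cKL = 2,
                        recKind = c("mse", "bce"), recDecayRate = 3e-5) {
  new("LossWeights", cRec = cRec, cReg = cReg, cKL = cKL,
      recKind = match.arg(recKind), recDecayRate = recDecayRate)
}

#' Augmentation settings
#'
#' @param cropScale crop side fraction (0.9 crops a 128-pixel image to 115
#'   pixels before resizing back).
#' @param smallRotationMaxDeg upper bound of the initial small rotation.
#' @param noiseAmplitude amplitude of the additive zero-centered noise map.
#' @param enableFlips,enableCrop,enableRotation90,enableSmallRotation,enableNoise
#'   per-step switches.
#' @return an [AugmentConfig-class].
#' @export
augmentConfig <- function(cropScale = 0.9, smallRotationMaxDeg = 5,
                          noiseAmplitude = 0.02, enableFlips = TRUE,
                          enableCrop = TRUE, enableRotation90 = TRUE,
                          enableSmallRotation = TRUE, enableNoise = TRUE) {
  new("AugmentConfig", cropScale = cropScale,
      smallRotationMaxDeg = smallRotationMaxDeg,
      noiseAmplitude = noiseAmplitude, enableFlips = enableFlips,
      enableCrop = enableCrop, enableRotation90 = enableRotation90,
      enableSmallRotation = enableSmallRotation, enableNoise = enableNoise)
}

#' Training configuration
#'
#' Defaults follow the published training recipe: Adam with a fixed
#' learning rate of 1.3e-4, decoupled weight decay 1e-5, a 100-epoch
#' regressor delay, and a 1:1 synthetic:natural ratio.  (The batch size
#' used in the study was 128 for phase-contrast and 64 for bright-field
#' runs; RAdam was preferred for bright-field data.)
#'
#' @param learningRate fixed learning rate.
#' @param weightDecay decoupled L2 coefficient per optimizer step.
#' @param optimizer `"adam"` or `"radam"`.
#' @param batchSize samples per step across both modalities.
#' @param maxEpochs maximum epochs (passes over the natural pool).
#' @param regressorDelayEpochs epochs before the regression term activates.
#' @param earlyStopPatience validation checks without improvement before
#'   stopping (0 disables early stopping).
#' @param validationEvery epochs between validation checks.
#' @param validationFraction labeled fraction per modality held out when no
#'   validation set is supplied.
#' @param synNatRatio synthetic samples per natural sample per epoch;
#'   values outside the validated 0.25-10 range trigger a warning.
#' @param seed master seed for sampling, augmentation and latent draws.
#' @param weightsNatural,weightsSynthetic per-modality [lossWeights()].
#' @param augment an [augmentConfig()], or `NULL` to disable augmentation.
#' @param decoderActive set `FALSE` to zero the reconstruction weight
#'   (decoder ablation during transfer).
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(learningRate = 1.3e-4, weightDecay = 1e-5,
                        optimizer = c("adam", "radam"), batchSize = 64,
                        maxEpochs = 100, regressorDelayEpochs = 100,
                        earlyStopPatience = 50, validationEvery = 10,
                        validationFraction = 0.1, synNatRatio = 1,
                        seed = 1, weightsNatural = lossWeights(),
                        weightsSynthetic = lossWeights(), augment = NULL,
                        decoderActive = TRUE) {
  if (synNatRatio < 0.25 || synNatRatio > 10)
    warning("synNatRatio ", synNatRatio,
            " is outside the validated range [0.25, 10]")
  new("TrainConfig", learningRate = learningRate, weightDecay = weightDecay,
      optimizer = match.arg(optimizer), batchSize = as.integer(batchSize),
      maxEpochs = as.integer(maxEpochs),
      regressorDelayEpochs = as.integer(regressorDelayEpochs),
      earlyStopPatience = as.integer(earlyStopPatience),
      validationEvery = as.integer(validationEvery),
      validationFraction = validationFraction, synNatRatio = synNatRatio,
      seed = as.integer(seed), weightsNatural = weightsNatural,
      weightsSynthetic = weightsSynthetic, augment = augment,
      decoderActive = decoderActive)
}

#' The named parts of the twin network
#'
#' The eight parts partition every trainable parameter: two outer encoders
#' and two outer decoders (modality-specific), the shared encoder stage,
#' the fully connected bottleneck, the shared decoder stage, and the
#' count-regression head.
#'
#' @return character vector of part names.
#' @export
networkParts <- function() as.character(eng_part_names())

#' Freeze plan for transfer learning
#'
#' @param scheme `"frozen_outer"`, `"frozen_core"`, `"simultaneous"` or
#'   `"thawing"`.
#' @param thawSchedule data.frame with columns `epoch` and `part`
#'   (thawing only).  When omitted for `"thawing"`, a default schedule
#'   unfreezes one outer part every `maxEpochs / 10` epochs.
#' @param baseScheme starting mask for `"thawing"`.
#' @param regressorFrozen also freeze the regression head.
#' @param maxEpochs used to build the default thaw schedule.
#' @return a [FreezePlan-class].
#' @examples
#' freezePlan("simultaneous")
#' freezePlan("thawing", maxEpochs = 1000)
#' @export
freezePlan <- function(scheme = c("simultaneous", "frozen_outer",
                                  "frozen_core", "thawing"),
                       thawSchedule = NULL, baseScheme = "frozen_outer",
                       regressorFrozen = FALSE, maxEpochs = 1000) {
  scheme <- match.arg(scheme)
  if (is.null(thawSchedule)) {
    thawSchedule <- if (scheme == "thawing") {
      step <- max(1L, as.integer(round(maxEpochs / 10)))
      outer <- c("outer_encoder_natural", "outer_encoder_synthetic",
                 "outer_decoder_natural", "outer_decoder_synthetic")
      data.frame(epoch = step * seq_along(outer), part = outer,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(epoch = integer(), part = character(),
                 stringsAsFactors = FALSE)
    }
  }
  new("FreezePlan", scheme = scheme, baseScheme = baseScheme,
      thawSchedule = thawSchedule, regressorFrozen = regressorFrozen)
}

# ---- accessors and methods ------------------------------------------------

#' Number of images in a set
#' @param x an [ImageSet-class].
#' @return integer count.
#' @export
nImages <- function(x) dim(x@images)[3]

#' Per-image labels of a set
#' @param x an [ImageSet-class].
#' @return integer vector (`NA` = unlabeled).
#' @export
sampleLabels <- function(x) x@label

#' @describeIn ImageSet-class subset images.
#' @param x,i,j,...,drop subsetting arguments; only `i` is used.
#' @export
setMethod("[", "ImageSet", function(x, i, j, ..., drop = FALSE) {
  new("ImageSet", images = x@images[, , i, drop = FALSE],
      label = x@label[i], modality = x@modality[i], style = x@style[i],
      id = x@id[i])
})

#' Combine image sets
#' @param x an [ImageSet-class].
#' @param ... further sets with the same resolution.
#' @export
setMethod("c", "ImageSet", function(x, ...) {
  sets <- c(list(x), list(...))
  res <- dim(x@images)[1]
  stopifnot(all(vapply(sets, function(s) dim(s@images)[1], 1L) == res))
  n <- sum(vapply(sets, nImages, 1L))
  arr <- array(0, c(res, res, n))
  at <- 0L
  for (s in sets) {
    k <- nImages(s)
    if (k > 0) arr[, , at + seq_len(k)] <- s@images
    at <- at + k
  }
  new("ImageSet", images = arr,
      label = unlist(lapply(sets, function(s) s@label)),
      modality = unlist(lapply(sets, function(s) s@modality)),
      style = unlist(lapply(sets, function(s) s@style)),
      id = unlist(lapply(sets, function(s) s@id)))
})

setMethod("show", "ImageSet", function(object) {
  d <- dim(object@images)
  cat(sprintf("ImageSet: %d image(s), %dx%d\n", d[3], d[1], d[2]))
  cat(sprintf("  labeled: %d, modalities: %s, styles: %s\n",
              sum(!is.na(object@label)),
              paste(unique(object@modality), collapse = "/"),
              paste(unique(object@style), collapse = "/")))
})

setMethod("show", "ImageSample", function(object) {
  cat(sprintf("ImageSample '%s': %dx%d, label %s, %s/%s\n", object@id,
              nrow(object@pixels), ncol(object@pixels),
              ifelse(is.na(object@label), "unlabeled", object@label),
              object@modality, object@style))
})

setMethod("show", "StylePreset", function(object) {
  cat(sprintf("StylePreset '%s': background %.2f, interior [%.2f, %.2f]\n",
              object@name, object@backgroundLevel,
              object@interiorBrightnessRange[1],
              object@interiorBrightnessRange[2]))
  if (!all(is.na(object@rimBrightnessRange)))
    cat(sprintf("  bright rim [%.2f, %.2f], width %.1f px\n",
                object@rimBrightnessRange[1], object@rimBrightnessRange[2],
                object@rimWidth))
  cat(sprintf("  semi-axes [%g, %g] px, blur [%g, %g] px, overlap p = %.2f\n",
              object@semiAxisRange[1], object@semiAxisRange[2],
              object@edgeBlurRange[1], object@edgeBlurRange[2],
              object@overlapProbability))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d cell(s), style %s, %dx%d, background %.2f, noise %.3f\n",
              nrow(object@cells), object@style, object@resolution,
              object@resolution, object@backgroundLevel, object@noiseAmplitude))
})

setMethod("show", "FreezePlan", function(object) {
  cat(sprintf("FreezePlan: %s%s\n", object@scheme,
              if (object@regressorFrozen) " (regressor frozen)" else ""))
  if (nrow(object@thawSchedule))
    cat(sprintf("  thaw: %s\n",
                paste(sprintf("%s@%d", object@thawSchedule$part,
                              object@thawSchedule$epoch), collapse = ", ")))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (n = %d)\n", object@n))
  cat(sprintf("  MAE: %.3f cells   MRE: %.2f%%   accuracy: %.1f%%\n",
              object@mae, object@mre, object@accuracy))
  if (!is.na(object@meanRecLoss))
    cat(sprintf("  mean reconstruction loss: %.5f\n", object@meanRecLoss))
})

setMethod("show", "TwinVAEModel", function(object) {
  info <- eng_info(object@ptr)
  cat(sprintf("TwinVAEModel: %dx%d input, width %g, latent %d, %s parameters\n",
              info$resolution, info$resolution, info$width, info$latent_dim,
              format(info$n_parameters, big.mark = ",")))
  cat(sprintf("  encoder channels %s + shared %d; epochs trained: %g\n",
              paste(info$encoder_channels, collapse = "/"),
              info$shared_channels, object@epoch))
})

setMethod("show", "DatasetManifest", function(object) {
  cat(sprintf("DatasetManifest (%s): %d row(s) at %s\n", object@split,
              nrow(object@data), object@root))
})
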