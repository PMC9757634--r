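#' @include TwinVAE-package.R
NULL

MODALITIES <- c("natural", "synthetic")
STYLES <- c("bf", "pc")

.checkRange <- function(x, nm, lo = -Inf, hi = Inf, len = 2) {
  if (length(x) != len || any(!is.finite(x))) {
    return(sprintf("%s must be %d finite values", nm, len))
  }
  if (len == 2 && x[1] > x[2]) return(sprintf("%s must be a valid interval", nm))
  if (any(x < lo) || any(x > hi)) {
    return(sprintf("%s must lie in [%g, %g]", nm, lo, hi))
  }
  NULL
}

#' StylePreset: parameter ranges of one synthetic visual style
#'
#' A preset bundles the sampling ranges of the synthetic-image generator for
#' one visual style.  Two presets ship with the package, emulating the two
#' light-microscopy modalities the counting network has to bridge:
#' `"bf"` (bright-field-like: cells slightly darker than a bright background,
#' no rim) and `"pc"` (phase-contrast-like: dark cell interior with the
#' characteristic bright halo, on a darker background).  All gray levels are
#' in `[0, 1]`, all lengths in pixels at a 128-pixel reference resolution
#' (geometry scales linearly when rendering at other resolutions).
#'
#' @slot name style tag, `"bf"` or `"pc"`.
#' @slot interiorBrightnessRange gray-level interval for cell interiors.
#' @slot rimBrightnessRange gray-level interval for the bright membrane halo
#'   (`c(NA, NA)` disables the rim, as in the bright-field preset).
#' @slot semiAxisRange ellipse semi-axis interval in pixels (at 128 px).
#' @slot deformationRange interval for the dimensionless contour-perturbation
#'   amplitude (at most 0.2: deformation stays below 20% of the semi-axis).
#' @slot edgeBlurRange per-cell Gaussian edge-blur sigma interval, pixels.
#' @slot backgroundLevel constant background gray level.
#' @slot noiseAmplitudeRange interval for the additive zero-centered noise
#'   standard deviation, gray-level units.
#' @slot overlapProbability probability that a newly placed cell is put
#'   within one cell diameter of an existing cell (mimicking divisions);
#'   otherwise placement is rejection-sampled to be disjoint.
#' @slot rimWidth rim thickness in pixels (pc style).
#' @seealso [stylePreset()], [sampleScene()], [renderScene()]
#' @exportClass StylePreset
setClass("StylePreset",
  representation(
    name = "character",
    interiorBrightnessRange = "numeric",
    rimBrightnessRange = "numeric",
    semiAxisRange = "numeric",
    deformationRange = "numeric",
    edgeBlurRange = "numeric",
    backgroundLevel = "numeric",
    noiseAmplitudeRange = "numeric",
    overlapProbability = "numeric",
    rimWidth = "numeric"
  ),
  validity = function(object) {
    errs <- c(
      if (!object@name %in% STYLES) "name must be 'bf' or 'pc'",
      .checkRange(object@interiorBrightnessRange, "interiorBrightnessRange", 0, 1),
      if (!all(is.na(object@rimBrightnessRange)))
        .checkRange(object@rimBrightnessRange, "rimBrightnessRange", 0, 1),
      .checkRange(object@semiAxisRange, "semiAxisRange", 0.5, 64),
      .checkRange(object@deformationRange, "deformationRange", 0, 0.2),
      .checkRange(object@edgeBlurRange, "edgeBlurRange", 0, 10),
      .checkRange(object@backgroundLevel, "backgroundLevel", 0, 1, len = 1),
      .checkRange(object@noiseAmplitudeRange, "noiseAmplitudeRange", 0, 0.5),
      .checkRange(object@overlapProbability, "overlapProbability", 0, 1, len = 1),
      .checkRange(object@rimWidth, "rimWidth", 0, 10, len = 1)
    )
    if (length(errs)) errs else TRUE
  }
)

#' SceneSpec: the generative description of one synthetic image
#'
#' A scene lists the cell primitives to draw plus background and noise
#' parameters.  Its ground-truth label is exactly `nrow(cells)`.  The
#' `cells` data frame has one row per cell with columns `row`, `col`
#' (center, 0-based pixel coordinates), `a`, `b` (semi-axes, pixels),
#' `rotation` (degrees), `deformation` (dimensionless amplitude),
#' `phase2`, `phase3` (radians, phases of the low-order radial contour
#' perturbation), `interior`, `rim` (gray levels; `rim = NA` means no rim)
#' and `blur` (edge-blur sigma, pixels).
#'
#' @slot cells data.frame of cell primitives (may have zero rows).
#' @slot backgroundLevel constant background gray level in `[0, 1]`.
#' @slot noiseAmplitude standard deviation of the additive noise.
#' @slot style `"bf"` or `"pc"`.
#' @slot resolution image side in pixels (a positive multiple of 32 for
#'   compatibility with the network; at least 32).
#' @slot seed integer seed used when rendering the noise map (`NA` to draw
#'   from the current RNG stream).
#' @seealso [sampleScene()], [renderScene()]
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(
    cells = "data.frame",
    backgroundLevel = "numeric",
    noiseAmplitude = "numeric",
    style = "character",
    resolution = "integer",
    seed = "integer"
  ),
  validity = function(object) {
    errs <- character()
    if (nrow(object@cells) > 30)
      errs <- c(errs, "a scene holds at most 30 cells")
    if (object@resolution < 32)
      errs <- c(errs, "resolution must be at least 32")
    if (!object@style %in% STYLES)
      errs <- c(errs, "style must be 'bf' or 'pc'")
    if (object@backgroundLevel < 0 || object@backgroundLevel > 1)
      errs <- c(errs, "backgroundLevel must be in [0, 1]")
    if (object@noiseAmplitude < 0)
      errs <- c(errs, "noiseAmplitude must be non-negative")
    if (nrow(object@cells) > 0) {
      need <- c("row", "col", "a", "b", "rotation", "deformation",
                "phase2", "phase3", "interior", "rim", "rimw", "blur")
      if (!all(need %in% names(object@cells)))
        errs <- c(errs, "cells is missing primitive columns")
      else {
        if (any(object@cells$a <= 0) || any(object@cells$b <= 0))
          errs <- c(errs, "semi-axes must be positive")
        if (any(pmax(object@cells$a, object@cells$b) > object@resolution / 2))
          errs <- c(errs, "cells must be small relative to the image side")
        bright <- c(object@cells$interior, object@cells$rim[!is.na(object@cells$rim)])
        if (any(bright < 0 | bright > 1))
          errs <- c(errs, "brightness values must be in [0, 1]")
      }
    }
    if (length(errs)) errs else TRUE
  }
)

#' ImageSample: one grayscale image with its annotations
#'
#' @slot pixels square matrix of gray levels in `[0, 1]`.
#' @slot label integer cell count (1-30 for annotated micrographs, 0 allowed
#'   for an empty rendered scene, `NA` when unlabeled).
#' @slot modality `"natural"` or `"synthetic"` — which twin of the network
#'   processes the image.
#' @slot style `"bf"` or `"pc"`.
#' @slot id identifier string.
#' @seealso [imageSample()], [renderScene()], [augmentSample()]
#' @exportClass ImageSample
setClass("ImageSample",
  representation(
    pixels = "matrix",
    label = "integer",
    modality = "character",
    style = "character",
    id = "character"
  ),
  validity = function(object) {
    errs <- character()
    if (nrow(object@pixels) != ncol(object@pixels))
      errs <- c(errs, "pixels must be square")
    rng <- range(object@pixels)
    if (rng[1] < 0 || rng[2] > 1)
      errs <- c(errs, "pixels must lie in [0, 1]")
    if (!is.na(object@label) && (object@label < 0 || object@label > 30))
      errs <- c(errs, "label must be in [0, 30] or NA")
    if (!object@modality %in% MODALITIES)
      errs <- c(errs, "modality must be 'natural' or 'synthetic'")
    if (!object@style %in% STYLES)
      errs <- c(errs, "style must be 'bf' or 'pc'")
    if (length(errs)) errs else TRUE
  }
)

#' ImageSet: a batch of equally sized grayscale images
#'
#' Column-oriented container used for training and evaluation: an
#' `resolution x resolution x n` array plus per-image label, modality, style
#' and id vectors.  Subset with `[` , combine with `c()`.
#'
#' @slot images numeric array `H x W x n`, values in `[0, 1]`.
#' @slot label integer vector (`NA` = unlabeled).
#' @slot modality character vector of `"natural"`/`"synthetic"`.
#' @slot style character vector of `"bf"`/`"pc"`.
#' @slot id character vector of identifiers.
#' @seealso [imageSet()], [generateImageSet()], [loadImageSet()]
#' @exportClass ImageSet
setClass("ImageSet",
  representation(
    images = "array",
    label = "integer",
    modality = "character",
    style = "character",
    id = "character"
  ),
  validity = function(object) {
    d <- dim(object@images)
    n <- length(object@label)
    errs <- character()
    if (length(d) != 3) errs <- c(errs, "images must be an H x W x n array")
    else {
      if (d[1] != d[2]) errs <- c(errs, "images must be square")
      if (d[3] != n) errs <- c(errs, "label length must match image count")
    }
    if (length(object@modality) != n || length(object@style) != n ||
        length(object@id) != n)
      errs <- c(errs, "annotation vectors must match image count")
    if (any(!is.na(object@label) & (object@label < 0 | object@label > 30)))
      errs <- c(errs, "labels must be in [0, 30] or NA")
    if (n > 0 && (min(object@images) < 0 || max(object@images) > 1))
      errs <- c(errs, "pixel values must lie in [0, 1]")
    if (length(errs)) errs else TRUE
  }
)

#' LossWeights: coefficients of the twin loss for one modality
#'
#' The twin objective for an input `x` with label `l` and modality `t` is
#' `cRec * Rec(x) + cReg * Reg(x, l) + cKL * KL(x)`, where the regression
#' weight is forced to zero for unlabeled images and during the regressor
#' delay.  With binary-cross-entropy reconstruction the effective `cRec`
#' decays multiplicatively per epoch (see [effectiveRecWeight()]).
#'
#' @slot cRec non-negative reconstruction weight.
#' @slot cReg non-negative count-regression weight.
#' @slot cKL non-negative Kullback-Leibler weight.
#' @slot recKind reconstruction loss kind, `"mse"` or `"bce"`.
#' @slot recDecayRate per-epoch decay rate of `cRec` (applied only for
#'   `"bce"`).
#' @seealso [lossWeights()], [twinLoss()]
#' @exportClass LossWeights
setClass("LossWeights",
  representation(cRec = "numeric", cReg = "numeric", cKL = "numeric",
                 recKind = "character", recDecayRate = "numeric"),
  validity = function(object) {
    errs <- c(
    if (object@cRec < 0 || object@cReg < 0 || object@cKL < 0)
      "loss weights must be non-negative",
    if (!object@recKind %in% c("mse", "bce"))
      "recKind must be 'mse' or 'bce'",
    if (object@recDecayRate < 0 || object@recDecayRate >= 1)
      "recDecayRate must be in [0, 1)")
    if (length(errs)) errs else TRUE
  }
)

#' AugmentConfig: the stochastic training augmentation stack
#'
#' Steps are applied in order: small rotation (uniform 0 to
#' `smallRotationMaxDeg` degrees), horizontal/vertical flips (each with
#' probability 1/2), random crop to `round(resolution * cropScale)` pixels
#' followed by bilinear resize back, a random 90-degree rotation
#' (probability 1/2), an additive zero-centered noise map scaled by
#' `noiseAmplitude`, and a final clip to `[0, 1]`.  Labels, modality and
#' style are never changed.
#'
#' @slot cropScale crop side as a fraction of the resolution (0.9 turns a
#'   128-pixel image into a 115-pixel crop).
#' @slot smallRotationMaxDeg upper bound of the small-rotation angle.
#' @slot noiseAmplitude amplitude of the uniform noise map.
#' @slot enableFlips,enableCrop,enableRotation90,enableSmallRotation,enableNoise
#'   per-step switches.
#' @seealso [augmentConfig()], [augmentSample()]
#' @exportClass AugmentConfig
setClass("AugmentConfig",
  representation(
    cropScale = "numeric", smallRotationMaxDeg = "numeric",
    noiseAmplitude = "numeric", enableFlips = "logical",
    enableCrop = "logical", enableRotation90 = "logical",
    enableSmallRotation = "logical", enableNoise = "logical"
  ),
  validity = function(object) {
    if (object@cropScale <= 0 || object@cropScale > 1)
      "cropScale must be in (0, 1]"
    else if (object@smallRotationMaxDeg < 0 || object@smallRotationMaxDeg > 45)
      "smallRotationMaxDeg must be in [0, 45]"
    else if (object@noiseAmplitude < 0) "noiseAmplitude must be non-negative"
    else TRUE
  }
)

#' FreezePlan: which network parts may train at a given epoch
#'
#' Freezing multiplies the would-be weight update of a part by zero (the
#' part also skips weight decay, so frozen parameters stay bit-identical);
#' gradients still flow through frozen parts to trainable ones.  Schemes:
#' `"frozen_outer"` (only the shared core trains), `"frozen_core"` (only
#' the modality-specific outer parts train), `"simultaneous"` (everything
#' trains) and `"thawing"` (start from a base scheme and unfreeze parts at
#' scheduled epochs).  The regression head trains under every scheme unless
#' `regressorFrozen` is set.
#'
#' @slot scheme one of `"frozen_outer"`, `"frozen_core"`, `"simultaneous"`,
#'   `"thawing"`.
#' @slot baseScheme base mask for `"thawing"`.
#' @slot thawSchedule data.frame with columns `epoch` (strictly increasing)
#'   and `part` (network part names, see [networkParts()]).
#' @slot regressorFrozen freeze the regression head as well.
#' @seealso [freezePlan()], [buildFreezeMask()], [transferTwinVAE()]
#' @exportClass FreezePlan
setClass("FreezePlan",
  representation(scheme = "character", baseScheme = "character",
                 thawSchedule = "data.frame", regressorFrozen = "logical"),
  validity = function(object) {
    schemes <- c("frozen_outer", "frozen_core", "simultaneous", "thawing")
    errs <- character()
    if (!object@scheme %in% schemes)
      errs <- c(errs, paste("scheme must be one of:", paste(schemes, collapse = ", ")))
    if (!object@baseScheme %in% setdiff(schemes, "thawing"))
      errs <- c(errs, "baseScheme must be a non-thawing scheme")
    ts <- object@thawSchedule
    if (nrow(ts) > 0) {
      if (!all(c("epoch", "part") %in% names(ts)))
        errs <- c(errs, "thawSchedule needs columns epoch and part")
      else {
        if (any(diff(ts$epoch) <= 0))
          errs <- c(errs, "thawSchedule epochs must be strictly increasing")
        if (!all(ts$part %in% networkParts()))
          errs <- c(errs, sprintf("unknown part in thawSchedule: %s",
                    paste(setdiff(ts$part, networkParts()), collapse = ", ")))
      }
    }
    if (length(errs)) errs else TRUE
  }
)

#' TrainConfig: optimizer, schedule and batching settings
#'
#' @slot learningRate fixed learning rate (no schedule).
#' @slot weightDecay decoupled L2 weight-decay coefficient applied at every
#'   optimizer step to trainable parts.
#' @slot optimizer `"adam"` or `"radam"` (rectified Adam).
#' @slot batchSize samples per optimization step (both modalities combined).
#' @slot maxEpochs maximum number of passes over the natural pool.
#' @slot regressorDelayEpochs epochs with the regression weight held at zero
#'   so early training learns pure reconstructions.
#' @slot earlyStopPatience number of consecutive validation checks without
#'   improvement of validation MAE before training stops (0 disables).
#' @slot validationEvery epochs between validation checks.
#' @slot validationFraction labeled fraction per modality held out when no
#'   explicit validation set is supplied.
#' @slot synNatRatio synthetic samples drawn per natural sample per epoch
#'   (validated range 0.25-10, values outside warn; 2 was found optimal for
#'   transfer, 1 keeps the two latent populations mixed).
#' @slot seed master seed; every random component derives a sub-stream.
#' @slot weightsNatural,weightsSynthetic per-modality [LossWeights-class].
#' @slot augment an [AugmentConfig-class], or `NULL` for no augmentation.
#' @slot decoderActive when `FALSE` the reconstruction weight is forced to
#'   zero (decoder-ablation mode for transfer experiments).
#' @seealso [trainConfig()], [trainTwinVAE()]
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(
    learningRate = "numeric", weightDecay = "numeric", optimizer = "character",
    batchSize = "integer", maxEpochs = "integer",
    regressorDelayEpochs = "integer", earlyStopPatience = "integer",
    validationEvery = "integer", validationFraction = "numeric",
    synNatRatio = "numeric", seed = "integer",
    weightsNatural = "LossWeights", weightsSynthetic = "LossWeights",
    augment = "ANY", decoderActive = "logical"
  ),
  validity = function(object) {
    errs <- c(
      if (object@learningRate <= 0) "learningRate must be positive",
      if (object@batchSize < 1) "batchSize must be at least 1",
      if (object@maxEpochs < 0) "maxEpochs must be non-negative",
      if (object@regressorDelayEpochs < 0) "regressorDelayEpochs must be non-negative",
      if (!object@optimizer %in% c("adam", "radam")) "optimizer must be 'adam' or 'radam'",
      if (object@synNatRatio <= 0) "synNatRatio must be positive",
      if (object@validationFraction < 0 || object@validationFraction >= 1)
        "validationFraction must be in [0, 1)",
      if (!is.null(object@augment) && !is(object@augment, "AugmentConfig"))
        "augment must be NULL or an AugmentConfig"
    )
    if (length(errs)) errs else TRUE
  }
)

#' TwinVAEModel: a handle on the twin network
#'
#' Wraps the native network state (an external pointer) together with its
#' architecture configuration, the epoch counter and the accumulated
#' training history.  Use [getCheckpoint()] / [twinVAEFromCheckpoint()] to
#' serialize; the external pointer itself does not survive `saveRDS()`.
#'
#' @slot ptr external pointer to the native network.
#' @slot config architecture configuration list (resolution, width,
#'   decoderChannels, seed, dropout, leak).
#' @slot epoch number of completed training epochs.
#' @slot history per-epoch training log (data.frame).
#' @slot best list with the best validation checkpoint seen during the last
#'   training run (`checkpoint`, `epoch`, `valMAE`), or an empty list.
#' @seealso [twinVAE()], [trainTwinVAE()], [evaluateModel()]
#' @exportClass TwinVAEModel
setClass("TwinVAEModel",
  representation(ptr = "externalptr", config = "list", epoch = "numeric",
                 history = "data.frame", best = "list"))

#' MetricsReport: count-prediction quality on an evaluation set
#'
#' @slot mae mean absolute error, in cells.
#' @slot mre mean relative error, percent of the true count.
#' @slot accuracy percent of predictions exactly correct after rounding
#'   (half away from zero).
#' @slot perCountMRE named numeric: MRE percent per true count.
#' @slot n number of labeled samples evaluated.
#' @slot meanRecLoss mean reconstruction loss over all (also unlabeled)
#'   samples, `NA` when not computed.
#' @seealso [computeMetrics()], [evaluateModel()]
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(mae = "numeric", mre = "numeric", accuracy = "numeric",
                 perCountMRE = "numeric", n = "integer",
                 meanRecLoss = "numeric"),
  validity = function(object) {
    if (object@mae < 0) "mae must be non-negative"
    else if (object@accuracy < 0 || object@accuracy > 100)
      "accuracy must be a percentage"
    else TRUE
  }
)

#' DatasetManifest: an on-disk image collection
#'
#' Rows of `(filename, label, modality, style)` anchored at a root
#' directory; `label` is `NA` for unlabeled images.  Canonical form is
#' sorted by filename.
#'
#' @slot data data.frame with columns `filename`, `label`, `modality`, `style`.
#' @slot root directory the filenames resolve against.
#' @slot split `"train"` or `"test"`.
#' @seealso [readManifest()], [writeManifest()], [loadImageSet()]
#' @exportClass DatasetManifest
setClass("DatasetManifest",
  representation(data = "data.frame", root = "character", split = "character"),
  validity = function(object) {
    errs <- character()
    need <- c("filename", "label", "modality", "style")
    if (!all(need %in% names(object@data)))
      errs <- c(errs, "manifest needs columns filename, label, modality, style")
    else {
      bad <- !is.na(object@data$label) &
        (object@data$label < 1 | object@data$label > 30)
      if (any(bad))
        errs <- c(errs, sprintf("labels must be integers in [1, 30]; offending row(s): %s",
                                paste(which(bad), collapse = ", ")))
      if (!all(object@data$modality %in% MODALITIES))
        errs <- c(errs, "modality must be 'natural' or 'synthetic'")
      if (!all(object@data$style %in% STYLES))
        errs <- c(errs, "style must be 'bf' or 'pc'")
    }
    if (!object@split %in% c("train", "test"))
      errs <- c(errs, "split must be 'train' or 'test'")
    if (length(errs)) errs else TRUE
  }
)
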