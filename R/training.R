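#' @include model.R
NULL

# bilinear sampling of img at continuous (row, col) positions (1-based);
# positions outside the canvas read the filled border value
.bilinear <- function(img, rowPos, colPos) {
  n <- nrow(img); m <- ncol(img)
  rowPos <- pmin(pmax(rowPos, 1), n)
  colPos <- pmin(pmax(colPos, 1), m)
  r0 <- pmin(floor(rowPos), n - 1L); c0 <- pmin(floor(colPos), m - 1L)
  fr <- rowPos - r0; fc <- colPos - c0
  i00 <- cbind(as.vector(r0), as.vector(c0))
  v <- (1 - fr) * (1 - fc) * img[i00] +
       fr * (1 - fc) * img[i00 + rep(c(1L, 0L), each = length(fr))] +
       (1 - fr) * fc * img[i00 + rep(c(0L, 1L), each = length(fr))] +
       fr * fc * img[i00 + 1L]
  matrix(v, nrow(rowPos), ncol(rowPos))
}

.rotateImage <- function(img, angleDeg, bg) {
  n <- nrow(img)
  th <- angleDeg * pi / 180
  ctr <- (n + 1) / 2
  g <- seq_len(n) - ctr
  y <- matrix(g, n, n); x <- matrix(g, n, n, byrow = TRUE)
  # inverse mapping: output pixel looks up source position
  rowPos <- ctr + y * cos(th) - x * sin(th)
  colPos <- ctr + y * sin(th) + x * cos(th)
  out <- .bilinear(img, rowPos, colPos)
  off <- rowPos < 1 | rowPos > n | colPos < 1 | colPos > n
  out[off] <- bg
  out
}

# side length of the intermediate random crop (e.g. 115 px for a 128-px
# image at the standard 0.9 crop scale)
.cropSide <- function(n, scale) as.integer(round(n * scale))

.resizeImage <- function(img, side) {
  n <- nrow(img)
  scale <- n / side
  pos <- (seq_len(side) - 0.5) * scale + 0.5
  .bilinear(img, matrix(pos, side, side), matrix(pos, side, side, byrow = TRUE))
}

#' Apply the stochastic training augmentation stack to one image
#'
#' Steps, in order (each subject to its enable flag): a small rotation by a
#' uniform 0 to `smallRotationMaxDeg` degrees (undefined corners filled
#' with the image median, mostly removed by the following crop);
#' horizontal and vertical flips, each with probability 1/2; a random crop
#' to `round(side * cropScale)` pixels at a uniform offset, scaled back to
#' the original side with bilinear interpolation; a 90-degree rotation
#' with probability 1/2; an additive zero-centered uniform noise map
#' scaled by `noiseAmplitude`; and a clip to `[0, 1]`.  The label,
#' modality and style tags are never modified.
#'
#' @param smp an [ImageSample-class] (or a plain pixel matrix).
#' @param cfg an [AugmentConfig-class].
#' @return object of the same type as `smp`; uses the current RNG stream.
#' @examples
#' set.seed(1)
#' img <- imageSample(matrix(runif(64^2), 64), label = 3)
#' out <- augmentSample(img, augmentConfig())
#' out@label  # unchanged
#' @export
augmentSample <- function(smp, cfg = augmentConfig()) {
  stopifnot(is(cfg, "AugmentConfig"))
  isSample <- is(smp, "ImageSample")
  img <- if (isSample) smp@pixels else smp
  n <- nrow(img)
  cropSide <- .cropSide(n, cfg@cropScale)
  if (cfg@enableCrop && cropSide < 1) stop("cropScale yields an empty crop")
  if (cfg@enableSmallRotation && cfg@smallRotationMaxDeg > 0)
    img <- .rotateImage(img, runif(1, 0, cfg@smallRotationMaxDeg), median(img))
  if (cfg@enableFlips) {
    if (runif(1) < 0.5) img <- img[rev(seq_len(n)), , drop = FALSE]
    if (runif(1) < 0.5) img <- img[, rev(seq_len(n)), drop = FALSE]
  }
  if (cfg@enableCrop && cropSide < n) {
    r0 <- sample.int(n - cropSide + 1L, 1L)
    c0 <- sample.int(n - cropSide + 1L, 1L)
    img <- .resizeImage(img[r0:(r0 + cropSide - 1L),
                            c0:(c0 + cropSide - 1L)], n)
  }
  if (cfg@enableRotation90 && runif(1) < 0.5)
    img <- t(img)[, rev(seq_len(n)), drop = FALSE]
  if (cfg@enableNoise && cfg@noiseAmplitude > 0)
    img <- img + matrix(runif(n * n, -1, 1) * cfg@noiseAmplitude, n, n)
  img <- pmin(pmax(img, 0), 1)
  if (isSample) {
    smp@pixels <- img
    smp
  } else img
}

# Assemble per-epoch mixed batches (index lists) honoring the syn:nat ratio.
.epochBatches <- function(nNat, nSyn, ratio, batchSize) {
  natOrder <- sample.int(nNat)
  nSynDraw <- as.integer(round(ratio * nNat))
  synOrder <- if (nSynDraw == 0L) integer(0)
    else if (nSynDraw <= nSyn) sample.int(nSyn)[seq_len(nSynDraw)]
    else sample.int(nSyn, nSynDraw, replace = TRUE)
  bN <- max(1L, min(batchSize - 1L, as.integer(round(batchSize / (1 + ratio)))))
  bS <- batchSize - bN
  batches <- list()
  iN <- 1L; iS <- 1L
  while (iN <= nNat || iS <= nSynDraw) {
    takeN <- if (iN <= nNat) natOrder[iN:min(nNat, iN + bN - 1L)] else integer(0)
    takeS <- if (iS <= nSynDraw) synOrder[iS:min(nSynDraw, iS + bS - 1L)] else integer(0)
    iN <- iN + length(takeN); iS <- iS + length(takeS)
    batches[[length(batches) + 1L]] <- list(natural = takeN, synthetic = takeS)
  }
  batches
}

.augmentMatrix <- function(mat, res, cfg) {
  for (j in seq_len(ncol(mat)))
    mat[, j] <- as.vector(augmentSample(matrix(mat[, j], res, res), cfg))
  mat
}

#' Train the twin network semi-supervised
#'
#' Each epoch visits every natural image once and draws
#' `round(synNatRatio * n_natural)` synthetic images (with replacement when
#' the synthetic pool is smaller), mixes both modalities within every batch
#' in the configured ratio, computes the twin loss with the per-modality
#' weights (regression weight zero for unlabeled images and during the
#' regressor delay) and steps the optimizer under the freeze plan's
#' gradient mask.  Validation mean absolute error is checked every
#' `validationEvery` epochs on a held-out labeled split (or the provided
#' validation sets) and drives early stopping and best-checkpoint
#' tracking.
#'
#' The run is deterministic for fixed data, configuration and seed:
#' batch order, augmentation, dropout and latent sampling all derive from
#' `config@seed`.
#'
#' @param model a [TwinVAEModel-class] (modified in place and returned).
#' @param natural training [ImageSet-class] routed to the natural twin; may
#'   mix labeled and unlabeled images.
#' @param synthetic fully labeled training [ImageSet-class] for the
#'   synthetic twin.
#' @param config a [TrainConfig-class].
#' @param plan a [FreezePlan-class]; thaw-schedule epochs count from the
#'   start of this run.
#' @param validation optional list with `natural` and/or `synthetic`
#'   [ImageSet-class] elements; when `NULL`, `validationFraction` of the
#'   labeled images per modality is held out.
#' @param historyFile optional path for a per-epoch CSV log.
#' @param verbose print a progress line per validation check.
#' @return the trained model; its `history` slot gains one row per epoch
#'   and `best` holds the best-validation checkpoint (`checkpoint`,
#'   `epoch`, `valMAE`).
#' @export
trainTwinVAE <- function(model, natural, synthetic, config = trainConfig(),
                         plan = freezePlan("simultaneous"),
                         validation = NULL, historyFile = NULL,
                         verbose = FALSE) {
  stopifnot(is(model, "TwinVAEModel"), is(config, "TrainConfig"),
            is(plan, "FreezePlan"))
  if (nImages(natural) == 0 || nImages(synthetic) == 0)
    stop("both training sets must be non-empty")
  if (any(is.na(synthetic@label)))
    stop("the synthetic training set must be fully labeled")
  res <- model@config$resolution

  # validation split
  if (is.null(validation) && config@validationFraction > 0) {
    validation <- list()
    splitOne <- function(set, nm) {
      lab <- which(!is.na(set@label))
      nVal <- floor(length(lab) * config@validationFraction)
      if (nVal < 1) return(set)
      vIdx <- withSeed(seedStream(config@seed, paste0("valsplit-", nm)),
                       sample(lab, nVal))
      validation[[nm]] <<- set[vIdx]
      set[-vIdx]
    }
    natural <- splitOne(natural, "natural")
    synthetic <- splitOne(synthetic, "synthetic")
  }
  valSet <- NULL
  if (!is.null(validation)) {
    parts <- Filter(Negate(is.null),
                    list(validation$natural, validation$synthetic))
    if (length(parts)) valSet <- Reduce(c, parts)
    if (!is.null(valSet)) {
      valSet <- valSet[!is.na(valSet@label)]
      if (nImages(valSet) == 0) valSet <- NULL
    }
  }

  xNat <- .flattenImages(natural)
  xSyn <- .flattenImages(synthetic)
  labNat <- as.numeric(natural@label)
  labSyn <- as.numeric(synthetic@label)

  optCode <- match(config@optimizer, c("adam", "radam")) - 1L
  kindCode <- function(w) match(w@recKind, c("mse", "bce")) - 1L
  partNames <- networkParts()

  eng_set_seed(model@ptr,
               seedStream(config@seed, paste0("engine-", model@epoch)))

  hist <- vector("list", config@maxEpochs)
  bestVal <- if (length(model@best)) model@best$valMAE else Inf
  best <- model@best
  badChecks <- 0L
  stopped <- FALSE

  for (e in seq_len(config@maxEpochs)) {
    runEpoch <- e - 1L           # epoch index within this run (0-based)
    globalEpoch <- model@epoch   # 0-based overall counter
    mask <- buildFreezeMask(plan, runEpoch)
    maskVec <- unname(mask[partNames])

    regOn <- runEpoch >= config@regressorDelayEpochs
    wN <- config@weightsNatural; wS <- config@weightsSynthetic
    cRecN <- if (config@decoderActive) effectiveRecWeight(wN, globalEpoch) else 0
    cRecS <- if (config@decoderActive) effectiveRecWeight(wS, globalEpoch) else 0
    regwN <- if (regOn) wN@cReg else 0
    regwS <- if (regOn) wS@cReg else 0

    batches <- withSeed(seedStream(config@seed, paste0("sampler-", globalEpoch)),
                        .epochBatches(ncol(xNat), ncol(xSyn),
                                      config@synNatRatio, config@batchSize))
    augSeed <- seedStream(config@seed, paste0("augment-", globalEpoch))

    comp <- c(total = 0, rec_natural = 0, rec_synthetic = 0, reg = 0,
              kl_natural = 0, kl_synthetic = 0)
    nb <- 0L
    withSeed(augSeed, for (b in batches) {
      xb <- xNat[, b$natural, drop = FALSE]
      sb <- xSyn[, b$synthetic, drop = FALSE]
      if (!is.null(config@augment)) {
        xb <- .augmentMatrix(xb, res, config@augment)
        sb <- .augmentMatrix(sb, res, config@augment)
      }
      lb <- labNat[b$natural]; ls <- labSyn[b$synthetic]
      rwN <- ifelse(is.na(lb), 0, regwN)
      rwS <- ifelse(is.na(ls), 0, regwS)
      r <- eng_train_batch(model@ptr, xb, ifelse(is.na(lb), 0, lb), rwN,
                           sb, ls, rwS,
                           cRecN, cRecS, kindCode(wN), kindCode(wS),
                           wN@cKL, wS@cKL,
                           config@learningRate, config@weightDecay, optCode,
                           0.9, 0.999, maskVec, TRUE)
      if (!is.finite(r$total))
        stop(sprintf("non-finite loss at epoch %d (rec %g/%g, reg %g, kl %g/%g)",
                     globalEpoch, r$rec_natural, r$rec_synthetic, r$reg,
                     r$kl_natural, r$kl_synthetic))
      for (f in names(comp)) comp[f] <- comp[f] + r[[f]]
      nb <- nb + 1L
    })
    comp <- comp / max(nb, 1L)
    model@epoch <- model@epoch + 1

    valMAE <- NA_real_; valAcc <- NA_real_
    checkNow <- !is.null(valSet) &&
      (e %% config@validationEvery == 0L || e == config@maxEpochs)
    if (checkNow) {
      pred <- predictCounts(model, valSet)
      mr <- computeMetrics(pred, valSet@label)
      valMAE <- mr@mae; valAcc <- mr@accuracy
      if (valMAE < bestVal) {
        bestVal <- valMAE
        best <- list(checkpoint = getCheckpoint(model, optimizer = FALSE),
                     epoch = model@epoch, valMAE = valMAE)
        badChecks <- 0L
      } else badChecks <- badChecks + 1L
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, val MAE %.3f, val acc %.1f%%",
                        model@epoch, comp["total"], valMAE, valAcc))
    }

    hist[[e]] <- data.frame(
      epoch = model@epoch, total = comp["total"],
      rec_natural = comp["rec_natural"], rec_synthetic = comp["rec_synthetic"],
      reg = comp["reg"], kl_natural = comp["kl_natural"],
      kl_synthetic = comp["kl_synthetic"],
      reg_weight_natural = regwN, reg_weight_synthetic = regwS,
      val_mae = valMAE, val_accuracy = valAcc,
      trainable = paste(partNames[maskVec], collapse = "+"),
      row.names = NULL)

    if (checkNow && config@earlyStopPatience > 0 &&
        badChecks >= config@earlyStopPatience) {
      stopped <- TRUE
      hist <- hist[seq_len(e)]
      break
    }
  }

  newHist <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  if (!is.null(newHist)) {
    model@history <- if (nrow(model@history)) rbind(model@history, newHist)
                     else newHist
  }
  model@best <- if (length(best)) best else list()
  if (!is.null(historyFile) && !is.null(newHist))
    write.csv(newHist, historyFile, row.names = FALSE)
  if (verbose && stopped)
    message("early stopping: no validation improvement for ",
            config@earlyStopPatience, " checks")
  model
}
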