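#' @include constructors.R
NULL

#' Build a twin variational autoencoder
#'
#' Constructs the Siamese network: per modality an outer encoder of four
#' 5x5 stride-2 convolutions (channels 32/64/128/256, leaky-ReLU slope 0.2,
#' dropout 0.1, orthogonal initialization), a shared fifth convolution with
#' 512 channels, a fully connected bottleneck 512 -> 256 -> 512 whose
#' 256-wide mean and log-variance heads form the variational latent code, a
#' shared transposed-convolution decoder stage with 256 channels followed
#' by batch normalization and leaky-ReLU, per-modality outer decoders of
#' five transposed convolutions with kernel sizes 5, 5, 5, 2, 6 (stride 2
#' except the fourth, sigmoid output), and one count-regression head (two
#' linear layers of sizes 256 and 128, dropout 0.1) fed by the spatially
#' averaged shared-decoder output and shared by both modalities.
#'
#' `width` scales every channel/feature count (0.25 gives encoder channels
#' 8/16/32/64 and a 64-dimensional latent code) so the architecture can be
#' exercised at desk scale; `width = 1` is the full published structure.
#'
#' @param resolution input image side in pixels; a positive multiple of 32
#'   (five stride-2 convolutions need the spatial map to stay integral).
#' @param width channel multiplier in (0, 1] or above.
#' @param decoderChannels four channel counts of the outer decoder's hidden
#'   layers; default `round(width * c(64, 32, 16, 16))`.
#' @param seed seed of the network's private RNG (initialization, dropout,
#'   latent sampling).
#' @param dropout dropout probability.
#' @param leak leaky-ReLU negative slope.
#' @return a [TwinVAEModel-class].
#' @examples
#' m <- twinVAE(resolution = 64, width = 0.25, seed = 1)
#' m
#' @export
twinVAE <- function(resolution = 128, width = 1, decoderChannels = NULL,
                    seed = 1, dropout = 0.1, leak = 0.2) {
  if (is.null(decoderChannels))
    decoderChannels <- pmax(1, round(width * c(64, 32, 16, 16)))
  stopifnot(length(decoderChannels) == 4)
  cfg <- list(resolution = as.integer(resolution), width = width,
              decoderChannels = as.integer(decoderChannels),
              seed = as.integer(seed), dropout = dropout, leak = leak)
  ptr <- eng_new(cfg$resolution, cfg$width, cfg$decoderChannels,
                 cfg$seed, cfg$dropout, cfg$leak)
  new("TwinVAEModel", ptr = ptr, config = cfg, epoch = 0,
      history = data.frame(), best = list())
}

.modalityCode <- function(modality) {
  match(match.arg(modality, MODALITIES), MODALITIES) - 1L
}

.flattenImages <- function(set, idx = seq_len(nImages(set))) {
  d <- dim(set@images)
  matrix(set@images[, , idx, drop = FALSE], d[1] * d[2], length(idx))
}

#' Encode images into latent codes
#'
#' Routes each image through the outer encoder of its modality, the shared
#' encoder and the bottleneck.  In evaluation mode (default) the latent
#' sample equals the mean, and repeated calls are identical; with
#' `sample = TRUE` the code is drawn by the reparameterization
#' `mean + exp(logvar / 2) * epsilon`.
#'
#' @param model a [TwinVAEModel-class].
#' @param x an [ImageSet-class], [ImageSample-class], or a pixel matrix.
#' @param modality used when `x` carries no modality annotation; images in
#'   a set are routed per their own modality tag.
#' @param sample draw a stochastic latent sample.
#' @param train use training mode (dropout active).
#' @return list with matrices `mean`, `logvar`, `sample`
#'   (`latent_dim x n`).
#' @export
encodeImages <- function(model, x, modality = c("natural", "synthetic"),
                         sample = FALSE, train = FALSE) {
  xs <- .asImageMatrix(model, x, modality)
  out <- list(mean = NULL, logvar = NULL, sample = NULL)
  for (m in 0:1) {
    idx <- which(xs$code == m)
    if (!length(idx)) next
    r <- eng_forward(model@ptr, xs$mat[, idx, drop = FALSE], m, train, sample)
    for (f in names(out)) {
      if (is.null(out[[f]]))
        out[[f]] <- matrix(NA_real_, nrow(r$mean), length(xs$code))
      out[[f]][, idx] <- r[[if (f == "sample") "sample" else f]]
    }
  }
  out
}

.asImageMatrix <- function(model, x, modality = c("natural", "synthetic")) {
  res <- model@config$resolution
  if (is(x, "ImageSet")) {
    if (dim(x@images)[1] != res)
      stop("image side ", dim(x@images)[1], " does not match model resolution ", res)
    list(mat = .flattenImages(x), code = match(x@modality, MODALITIES) - 1L)
  } else if (is(x, "ImageSample")) {
    if (nrow(x@pixels) != res)
      stop("image side ", nrow(x@pixels), " does not match model resolution ", res)
    list(mat = matrix(as.vector(x@pixels), ncol = 1),
         code = match(x@modality, MODALITIES) - 1L)
  } else {
    x <- as.matrix(x)
    if (nrow(x) == res && ncol(x) == res) x <- matrix(as.vector(x), ncol = 1)
    else if (nrow(x) != res * res) stop("pixel matrix does not match model resolution")
    list(mat = x, code = rep(.modalityCode(modality), ncol(x)))
  }
}

#' Decode latent codes into images
#'
#' Runs the shared decoder stage and the outer decoder of the requested
#' modality.  The final sigmoid keeps every pixel in `[0, 1]`.
#'
#' @param model a [TwinVAEModel-class].
#' @param latent `latent_dim x n` matrix (or a vector for one image).
#' @param modality which outer decoder to use.
#' @return `resolution^2 x n` matrix of pixels in `[0, 1]`.
#' @export
decodeLatent <- function(model, latent, modality = c("natural", "synthetic")) {
  latent <- as.matrix(latent)
  eng_decode(model@ptr, latent, .modalityCode(modality))
}

#' Full forward pass: reconstruction, predicted count and latent code
#'
#' @param model a [TwinVAEModel-class].
#' @param x images (see [encodeImages()]).
#' @param modality fallback modality for raw matrices.
#' @param sample,train stochastic latent sampling / training mode.
#' @return list with `reconstruction` (pixels x n, in `[0, 1]`),
#'   `predictedCount` (numeric n), and `latent` (list `mean`, `logvar`,
#'   `sample`).
#' @export
twinForward <- function(model, x, modality = c("natural", "synthetic"),
                        sample = FALSE, train = FALSE) {
  xs <- .asImageMatrix(model, x, modality)
  n <- length(xs$code)
  P <- model@config$resolution^2
  rec <- matrix(NA_real_, P, n)
  cnt <- numeric(n)
  mu <- lv <- zz <- NULL
  for (m in 0:1) {
    idx <- which(xs$code == m)
    if (!length(idx)) next
    r <- eng_forward(model@ptr, xs$mat[, idx, drop = FALSE], m, train, sample)
    rec[, idx] <- r$reconstruction
    cnt[idx] <- as.numeric(r$count)
    if (is.null(mu)) {
      mu <- matrix(NA_real_, nrow(r$mean), n)
      lv <- mu; zz <- mu
    }
    mu[, idx] <- r$mean; lv[, idx] <- r$logvar; zz[, idx] <- r$sample
  }
  list(reconstruction = rec, predictedCount = cnt,
       latent = list(mean = mu, logvar = lv, sample = zz))
}

#' Predict cell counts for an image set
#'
#' Deterministic evaluation-mode forward pass (no dropout, latent sample =
#' mean), processed in chunks.
#'
#' @param model a [TwinVAEModel-class].
#' @param set an [ImageSet-class].
#' @param chunk images per forward pass.
#' @return numeric vector of raw (unrounded) predicted counts.
#' @export
predictCounts <- function(model, set, chunk = 64L) {
  n <- nImages(set)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    out[idx] <- twinForward(model, set[idx])$predictedCount
  }
  out
}

# ---- loss primitives -----------------------------------------------------

#' Reconstruction loss between an image and its decoded reconstruction
#'
#' `"mse"` is the pixel mean of the squared difference; `"bce"` is the
#' pixel mean of the binary cross-entropy
#' `-(x log d + (1 - x) log(1 - d))`, with the reconstruction clamped to
#' `[1e-7, 1 - 1e-7]` for numerical safety.
#'
#' @param x,d numeric arrays of identical shape, values in `[0, 1]`.
#' @param kind `"mse"` or `"bce"`.
#' @return scalar loss (mean over pixels).
#' @examples
#' reconstructionLoss(matrix(1, 2, 2), matrix(0.5, 2, 2), "mse")  # 0.25
#' reconstructionLoss(matrix(1, 2, 2), matrix(0.5, 2, 2), "bce")  # log(2)
#' @export
reconstructionLoss <- function(x, d, kind = c("mse", "bce")) {
  kind <- match.arg(kind)
  if (!all(dim(as.array(x)) == dim(as.array(d))))
    stop("x and d must have identical shape")
  if (kind == "mse") return(mean((x - d)^2))
  d <- pmin(pmax(d, 1e-7), 1 - 1e-7)
  mean(-(x * log(d) + (1 - x) * log(1 - d)))
}

#' Count-regression loss
#'
#' Squared error `(l - r)^2` between the true count and the regressor
#' output.  Calling it on an unlabeled sample is a contract violation: the
#' caller must zero the regression weight instead.
#'
#' @param label true cell count.
#' @param predicted regressor output.
#' @return scalar squared error.
#' @export
regressionLoss <- function(label, predicted) {
  if (any(is.na(label)))
    stop("regression loss is undefined for unlabeled samples; set the regression weight to zero instead")
  (label - predicted)^2
}

#' Kullback-Leibler divergence of diagonal-Gaussian latent codes
#'
#' The standard VAE regularizer against the standard normal prior:
#' `-0.5 * sum(1 + logvar - mean^2 - exp(logvar))` per sample (summed over
#' latent dimensions), averaged over the batch.  Always non-negative and
#' zero exactly at the standard normal.
#'
#' @param mean,logvar vectors, or matrices with one column per sample.
#' @return scalar divergence.
#' @examples
#' klDivergence(0, 0)      # 0
#' klDivergence(1, 0)      # 0.5
#' @export
klDivergence <- function(mean, logvar) {
  mean <- as.matrix(mean); logvar <- as.matrix(logvar)
  if (!all(dim(mean) == dim(logvar))) stop("mean and logvar must match")
  per <- -0.5 * colSums(1 + logvar - mean^2 - exp(logvar))
  base::mean(per)
}

#' Effective reconstruction weight at an epoch
#'
#' With binary-cross-entropy reconstruction, `cRec` decays multiplicatively
#' as `cRec * (1 - recDecayRate)^epoch`, so the slowly shrinking BCE term
#' progressively amplifies the regression term; with `"mse"` the weight is
#' constant.
#'
#' @param weights a [LossWeights-class].
#' @param epoch zero-based epoch counter.
#' @return scalar effective weight.
#' @export
effectiveRecWeight <- function(weights, epoch = 0) {
  if (weights@recKind == "bce")
    weights@cRec * (1 - weights@recDecayRate)^epoch
  else weights@cRec
}

#' The twin loss: weighted sum of reconstruction, regression and KL terms
#'
#' Combines pre-computed component losses as
#' `cRec(epoch) * rec + cReg * reg + cKL * kl`.  The regression weight is
#' treated as zero when the sample is unlabeled (`labeled = FALSE` or
#' `reg = NA`).
#'
#' @param rec reconstruction loss component.
#' @param reg regression loss component (`NA` for unlabeled samples).
#' @param kl KL-divergence component.
#' @param weights a [LossWeights-class].
#' @param epoch zero-based epoch (drives the BCE decay of `cRec`).
#' @param labeled whether the sample's count is known.
#' @return scalar loss.
#' @examples
#' w <- lossWeights(cRec = 100, cReg = 3, cKL = 2)
#' twinLoss(0.01, 4, 0.5, w)  # 14
#' @export
twinLoss <- function(rec, reg, kl, weights, epoch = 0, labeled = TRUE) {
  stopifnot(is(weights, "LossWeights"))
  cRec <- effectiveRecWeight(weights, epoch)
  if (cRec < 0) stop("effective reconstruction weight is negative")
  cReg <- if (labeled && !is.na(reg)) weights@cReg else 0
  reg <- if (is.na(reg)) 0 else reg
  cRec * rec + cReg * reg + weights@cKL * kl
}

#' Twin loss of a forward pass on one sample
#'
#' Computes the three components from network outputs and combines them
#' with [twinLoss()].
#'
#' @param outputs result of [twinForward()] for a single image.
#' @param sampleObj the [ImageSample-class] that was passed in.
#' @param weights a [LossWeights-class] for the sample's modality.
#' @param epoch zero-based epoch.
#' @return list with `total`, `rec`, `reg`, `kl`.
#' @export
twinLossFromOutputs <- function(outputs, sampleObj, weights, epoch = 0) {
  labeled <- !is.na(sampleObj@label)
  rec <- reconstructionLoss(as.vector(sampleObj@pixels),
                            as.vector(outputs$reconstruction),
                            weights@recKind)
  reg <- if (labeled)
    regressionLoss(sampleObj@label, outputs$predictedCount[1]) else NA_real_
  kl <- klDivergence(outputs$latent$mean, outputs$latent$logvar)
  list(total = twinLoss(rec, reg, kl, weights, epoch, labeled),
       rec = rec, reg = reg, kl = kl)
}
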