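#' @include model.R
NULL

# round half away from zero (3.5 -> 4, -3.5 -> -4), the rounding used for
# counting accuracy
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Count-prediction metrics
#'
#' Computes the mean absolute error (cells), the mean relative error
#' (percent of the true count), the accuracy (percent of predictions that
#' match the label exactly after rounding half away from zero), and the
#' per-count MRE breakdown.
#'
#' @param predictions numeric vector of raw predicted counts.
#' @param labels integer vector of true counts (all at least 1).
#' @return a [MetricsReport-class].
#' @examples
#' computeMetrics(c(2, 2), c(1, 4))  # MAE 1.5, MRE 75%, accuracy 0%
#' @export
computeMetrics <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length")
  if (length(predictions) == 0) stop("empty evaluation set")
  if (any(is.na(labels))) stop("labels must be known")
  if (any(labels < 1))
    stop("labels must be at least 1 (relative error is undefined at 0)")
  err <- abs(predictions - labels)
  rel <- err / labels * 100
  perCount <- vapply(split(rel, labels), mean, 0)
  new("MetricsReport",
      mae = mean(err), mre = mean(rel),
      accuracy = 100 * mean(roundHalfAway(predictions) == labels),
      perCountMRE = perCount, n = length(labels),
      meanRecLoss = NA_real_)
}

#' Evaluate a model on a data set
#'
#' Runs a deterministic forward pass (no dropout, no latent sampling, no
#' augmentation) on every image, aggregates [computeMetrics()] over the
#' labeled ones and reports the mean reconstruction loss over all images,
#' including unlabeled ones.
#'
#' @param model a [TwinVAEModel-class].
#' @param data an [ImageSet-class] or a [DatasetManifest-class].
#' @param recKind reconstruction loss used for the report.
#' @param chunk images per forward pass.
#' @return a [MetricsReport-class].
#' @export
evaluateModel <- function(model, data, recKind = c("mse", "bce"), chunk = 64L) {
  recKind <- match.arg(recKind)
  if (is(data, "DatasetManifest")) data <- loadImageSet(data)
  stopifnot(is(data, "ImageSet"))
  n <- nImages(data)
  labeled <- which(!is.na(data@label))
  if (!length(labeled)) stop("no labeled samples to evaluate")
  pred <- numeric(n)
  recLoss <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    sub <- data[idx]
    out <- twinForward(model, sub)
    pred[idx] <- out$predictedCount
    x <- .flattenImages(sub)
    for (k in seq_along(idx))
      recLoss[idx[k]] <- reconstructionLoss(x[, k], out$reconstruction[, k],
                                            recKind)
  }
  rep <- computeMetrics(pred[labeled], data@label[labeled])
  rep@meanRecLoss <- mean(recLoss)
  rep
}

#' Cross-decoder reconstruction
#'
#' Encodes an image with the outer encoder of its own modality and decodes
#' the latent mean with the outer decoder of the other (or any requested)
#' modality.  A well-trained shared representation keeps cell count,
#' positions and sizes intact across the swap — the package's main
#' diagnostic that natural and synthetic data share one latent space.
#' When `target` equals the sample's own modality this reduces exactly to
#' the ordinary reconstruction path.
#'
#' @param model a [TwinVAEModel-class].
#' @param smp an [ImageSample-class] (or [ImageSet-class] of one modality).
#' @param target modality whose decoder renders the image.
#' @return pixel matrix in `[0, 1]` (or a `pixels x n` matrix for a set).
#' @export
crossDecode <- function(model, smp, target = c("synthetic", "natural")) {
  target <- match.arg(target)
  enc <- encodeImages(model, smp)
  out <- decodeLatent(model, enc$mean, target)
  if (is(smp, "ImageSample")) {
    res <- model@config$resolution
    matrix(out[, 1], res, res)
  } else out
}

#' Count connected components above/below a threshold
#'
#' Simple component-counting oracle for rendered or reconstructed images:
#' binarizes with the given polarity (`"dark"` objects below, `"bright"`
#' objects above the threshold) and counts connected components of at
#' least `minSize` pixels using [EBImage::bwlabel()].  The default
#' threshold is the midpoint between the image median (background) and the
#' relevant extreme.
#'
#' @param pixels numeric matrix in `[0, 1]`.
#' @param polarity `"dark"` for objects below the threshold (cell
#'   interiors in both shipped styles), `"bright"` for objects above it.
#' @param threshold binarization threshold, or `NULL` for the default.
#' @param minSize minimum component area in pixels.
#' @param smoothSigma Gaussian pre-smoothing sigma in pixels (0 disables);
#'   smoothing suppresses noise speckle before thresholding and makes the
#'   count robust on noisy renderings.
#' @return integer component count.
#' @export
countComponents <- function(pixels, polarity = c("dark", "bright"),
                            threshold = NULL, minSize = 4L,
                            smoothSigma = 0) {
  polarity <- match.arg(polarity)
  if (smoothSigma > 0)
    pixels <- EBImage::imageData(EBImage::gblur(pixels, sigma = smoothSigma))
  med <- median(pixels)
  if (is.null(threshold))
    threshold <- if (polarity == "dark") (med + min(pixels)) / 2
                 else (med + max(pixels)) / 2
  mask <- if (polarity == "dark") pixels < threshold else pixels > threshold
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  sizes <- table(as.vector(EBImage::imageData(lab)))
  sizes <- sizes[names(sizes) != "0"]
  sum(sizes >= minSize)
}

#' Two-dimensional latent embedding of data sets
#'
#' Collects the latent mean of every image (deterministic encoding) and
#' projects the codes to two dimensions with UMAP (seeded, single
#' threaded, so coordinates are reproducible).  The returned table carries
#' the annotations used in the standard diagnostic plot: modality, label
#' presence and cell count.
#'
#' @param model a [TwinVAEModel-class].
#' @param data an [ImageSet-class] (combine sets with `c()` first), at
#'   least 10 images.
#' @param seed seed of the projection.
#' @param nNeighbors UMAP neighborhood size (capped at `n - 1`).
#' @return data.frame with columns `x`, `y`, `modality`, `labeled`,
#'   `count`, `style`, `id`.
#' @export
embedDataset <- function(model, data, seed = 1, nNeighbors = 15) {
  stopifnot(is(data, "ImageSet"))
  n <- nImages(data)
  if (n < 10) stop("need at least 10 samples to embed, got ", n)
  codes <- t(encodeImages(model, data)$mean)
  coords <- withSeed(seed,
    uwot::umap(codes, n_neighbors = min(nNeighbors, n - 1),
               n_threads = 1, n_sgd_threads = 0))
  data.frame(x = coords[, 1], y = coords[, 2],
             modality = data@modality, labeled = !is.na(data@label),
             count = data@label, style = data@style, id = data@id,
             stringsAsFactors = FALSE)
}
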