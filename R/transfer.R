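#' @include training.R
NULL

#' Trainability mask of the network parts at an epoch
#'
#' Resolves a [FreezePlan-class] to a named logical vector over
#' [networkParts()].  `"frozen_outer"` trains only the shared core (shared
#' encoder, bottleneck, shared decoder); `"frozen_core"` trains only the
#' modality-specific outer parts; `"simultaneous"` trains everything;
#' `"thawing"` starts from its base scheme and switches scheduled parts to
#' trainable once their epoch is reached.  The regression head is
#' trainable under every scheme unless the plan freezes it.
#'
#' @param plan a [FreezePlan-class].
#' @param epoch zero-based epoch within the training run.
#' @return named logical vector (`TRUE` = trainable).
#' @examples
#' buildFreezeMask(freezePlan("frozen_core"), 0)
#' @export
buildFreezeMask <- function(plan, epoch = 0) {
  stopifnot(is(plan, "FreezePlan"), epoch >= 0)
  parts <- networkParts()
  outer <- grepl("^outer_", parts)
  shared <- parts %in% c("shared_encoder", "bottleneck", "shared_decoder")
  base <- if (plan@scheme == "thawing") plan@baseScheme else plan@scheme
  mask <- switch(base,
    frozen_outer = !outer,
    frozen_core = !shared,
    simultaneous = rep(TRUE, length(parts)))
  names(mask) <- parts
  if (plan@scheme == "thawing" && nrow(plan@thawSchedule)) {
    due <- plan@thawSchedule$epoch <= epoch
    mask[plan@thawSchedule$part[due]] <- TRUE
  }
  mask["regressor"] <- !plan@regressorFrozen
  mask
}

#' Mixed-modality batch plan for one epoch
#'
#' Every natural image is visited exactly once per epoch; the number of
#' synthetic draws is `round(ratio * n_natural)`, taken without
#' replacement when the synthetic pool is large enough and with
#' replacement otherwise.  Each batch contains both modalities in the
#' configured ratio (rounded), so the shared layers see both data
#' distributions at every step.
#'
#' @param natural,synthetic [ImageSet-class] objects (or integer pool
#'   sizes).
#' @param ratio synthetic:natural ratio (positive; the validated range is
#'   0.25 to 10).
#' @param batchSize total samples per batch.
#' @return list of batches, each a list with integer index vectors
#'   `natural` and `synthetic`; uses the current RNG stream.
#' @examples
#' set.seed(1)
#' b <- mixedBatchSampler(100, 200, ratio = 2, batchSize = 30)
#' sum(lengths(lapply(b, `[[`, "synthetic")))  # 200 synthetic draws
#' @export
mixedBatchSampler <- function(natural, synthetic, ratio = 1, batchSize = 64) {
  nNat <- if (is(natural, "ImageSet")) nImages(natural) else as.integer(natural)
  nSyn <- if (is(synthetic, "ImageSet")) nImages(synthetic) else as.integer(synthetic)
  if (nNat < 1 || nSyn < 1) stop("both pools must be non-empty")
  if (ratio <= 0) stop("ratio must be positive")
  if (ratio < 0.25 || ratio > 10)
    warning("ratio ", ratio, " is outside the validated range [0.25, 10]")
  .epochBatches(nNat, nSyn, ratio, as.integer(batchSize))
}

#' Apply one optimizer step with injected unit gradients
#'
#' Sets the gradient of every parameter to one and applies the optimizer
#' under the freeze mask.  Parameters of masked-off parts stay
#' bit-identical (they are also exempt from weight decay); all others
#' change.  This is the freeze-contract probe used by the test suite; it
#' does not compute a real gradient.
#'
#' @param model a [TwinVAEModel-class] (modified in place).
#' @param mask named logical vector from [buildFreezeMask()].
#' @param learningRate,weightDecay optimizer settings.
#' @param optimizer `"adam"` or `"radam"`.
#' @return the model, invisibly.
#' @export
maskedStep <- function(model, mask, learningRate = 1e-3, weightDecay = 0,
                       optimizer = c("adam", "radam")) {
  optCode <- match(match.arg(optimizer), c("adam", "radam")) - 1L
  eng_ones_step(model@ptr, learningRate, weightDecay, optCode, 0.9, 0.999,
                unname(mask[networkParts()]))
  invisible(model)
}

#' Transfer a trained network to a new imaging domain
#'
#' Initializes every part (both outer twins included) from the source
#' checkpoint, then continues training on the target-domain data under the
#' freeze plan's gradient mask.  With `plan = freezePlan("simultaneous")`
#' and the same seed this is exactly `trainTwinVAE()` started from the
#' checkpoint.
#'
#' @param source a checkpoint (from [getCheckpoint()]) or a
#'   [TwinVAEModel-class].
#' @param natural,synthetic target-domain training sets.
#' @param plan a [FreezePlan-class].
#' @param config a [TrainConfig-class].
#' @param ... passed on to [trainTwinVAE()] (`validation`, `historyFile`,
#'   `verbose`).
#' @return the transferred [TwinVAEModel-class]; its history records which
#'   parts were trainable each epoch.
#' @export
transferTwinVAE <- function(source, natural, synthetic, plan, config, ...) {
  ckpt <- if (is(source, "TwinVAEModel")) getCheckpoint(source) else source
  model <- twinVAEFromCheckpoint(ckpt, resetOptimizer = TRUE)
  model@history <- data.frame()
  trainTwinVAE(model, natural, synthetic, config, plan, ...)
}

#' Double transfer: A to B, then back to A
#'
#' Runs [transferTwinVAE()] towards domain B, then transfers the result
#' back to domain A.  Pretraining on the richer domain, adapting to the
#' poorer one and returning yields the strongest starting point on A.
#'
#' @param source checkpoint or model pretrained on domain A.
#' @param naturalB,syntheticB domain-B training sets.
#' @param naturalA,syntheticA domain-A training sets.
#' @param plan a [FreezePlan-class] used for both stages.
#' @param config a [TrainConfig-class] used for both stages.
#' @param ... passed to [transferTwinVAE()].
#' @return list with `model` (final [TwinVAEModel-class]), `history`
#'   (both stage histories with a `stage` column), and `stageB` (the
#'   intermediate domain-B model).
#' @export
doubleTransfer <- function(source, naturalB, syntheticB, naturalA, syntheticA,
                           plan, config, ...) {
  mB <- transferTwinVAE(source, naturalB, syntheticB, plan, config, ...)
  mA <- transferTwinVAE(mB, naturalA, syntheticA, plan, config, ...)
  hb <- mB@history; ha <- mA@history
  if (nrow(hb)) hb$stage <- "A_to_B"
  if (nrow(ha)) ha$stage <- "B_to_A"
  list(model = mA, history = rbind(hb, ha), stageB = mB)
}
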