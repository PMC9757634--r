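#' @include model.R
NULL

#' Extract a checkpoint from a model
#'
#' The checkpoint holds every parameter keyed by the eight network part
#' names (plus the batch-normalization running statistics), the optimizer
#' moments and step counter, the architecture configuration and the epoch
#' counter.  Restoring it reproduces the network bit-exactly.
#'
#' @param model a [TwinVAEModel-class].
#' @param optimizer include optimizer state (needed for exact training
#'   resumption).
#' @return a list with elements `state`, `optimizer`, `config`, `epoch`.
#' @seealso [twinVAEFromCheckpoint()], [writeCheckpoint()]
#' @export
getCheckpoint <- function(model, optimizer = TRUE) {
  list(state = eng_get_state(model@ptr),
       optimizer = if (optimizer) eng_get_opt_state(model@ptr),
       config = model@config, epoch = model@epoch)
}

#' Rebuild a model from a checkpoint
#'
#' @param checkpoint a list from [getCheckpoint()] or [readCheckpoint()].
#' @param resetOptimizer discard optimizer moments (fresh optimizer for a
#'   new training phase).
#' @return a [TwinVAEModel-class].
#' @export
twinVAEFromCheckpoint <- function(checkpoint, resetOptimizer = FALSE) {
  cfg <- checkpoint$config
  model <- twinVAE(resolution = cfg$resolution, width = cfg$width,
                   decoderChannels = cfg$decoderChannels, seed = cfg$seed,
                   dropout = cfg$dropout, leak = cfg$leak)
  eng_set_state(model@ptr, checkpoint$state)
  if (!is.null(checkpoint$optimizer) && !resetOptimizer)
    eng_set_opt_state(model@ptr, checkpoint$optimizer)
  model@epoch <- checkpoint$epoch
  model
}

#' Restore checkpointed parameters into an existing model
#'
#' The checkpoint must come from an architecture-compatible model
#' (identical resolution, width and decoder channels); otherwise a
#' checkpoint-incompatibility error names the offending tensor.
#'
#' @param model a [TwinVAEModel-class].
#' @param checkpoint from [getCheckpoint()].
#' @return the model, invisibly (modified in place).
#' @export
setCheckpoint <- function(model, checkpoint) {
  eng_set_state(model@ptr, checkpoint$state)
  if (!is.null(checkpoint$optimizer))
    eng_set_opt_state(model@ptr, checkpoint$optimizer)
  model@epoch <- checkpoint$epoch
  invisible(model)
}

#' Write / read a checkpoint file
#'
#' Checkpoints are serialized with `saveRDS`; numeric parameters round-trip
#' bit-exactly.
#'
#' @param checkpoint from [getCheckpoint()] (or a [TwinVAEModel-class],
#'   which is converted first).
#' @param path file path.
#' @return `readCheckpoint` returns the checkpoint list.
#' @export
writeCheckpoint <- function(checkpoint, path) {
  if (is(checkpoint, "TwinVAEModel")) checkpoint <- getCheckpoint(checkpoint)
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint file not found: ", path)
  readRDS(path)
}
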