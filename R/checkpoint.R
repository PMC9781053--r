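#' Save a self-describing model checkpoint
#'
#' Stores weights, batch-norm running statistics, the architecture
#' descriptor and both configurations, so a checkpoint (including a
#' pruned one) reloads without external metadata.
#'
#' @param model A `pcenet_model`.
#' @param path Output file (conventionally `.ckpt` or `.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pcenet_model"))
  saveRDS(list(format = "pcenet-checkpoint-1",
               arch = model$arch,
               params = model$params,
               buffers = model$buffers,
               config = model$config,
               provenance = model$provenance),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return The restored `pcenet_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("load_checkpoint: no such file: ", path)
  x <- readRDS(path)
  if (!identical(x$format, "pcenet-checkpoint-1"))
    stop("load_checkpoint: ", path, " is not a recognized checkpoint")
  structure(list(arch = x$arch, params = x$params, buffers = x$buffers,
                 config = x$config, provenance = x$provenance),
            class = "pcenet_model")
}
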