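#' Count trainable parameters
#'
#' Enumerates every trainable tensor (convolution and linear weights,
#' biases, batch-norm scale/shift; running statistics are buffers, not
#' parameters) and totals them.
#'
#' @param model A `pcenet_model`, a `model_param_spec` (architecture
#'   shape enumeration, e.g. [mobilenet_v3_large()]), or a named list of
#'   parameter arrays.
#' @param bytes_per_param Bytes per parameter used for the serialized
#'   size estimate (4 or 8).
#' @return Object of class `model_audit` with a per-tensor table,
#'   `total_params`, `total_params_millions` (rounded to 2 decimals) and
#'   `est_size_mb`.
#' @export
#' @examples
#' count_parameters(list(W = matrix(0, 128, 7), b = numeric(7)))
count_parameters <- function(model, bytes_per_param = 4L) {
  shapes <- param_shapes(model)
  counts <- vapply(shapes, prod, 1)
  layers <- data.frame(
    name = names(shapes),
    shape = vapply(shapes, function(d) paste(d, collapse = "x"), ""),
    params = as.numeric(counts),
    stringsAsFactors = FALSE)
  total <- sum(counts)
  structure(list(layers = layers,
                 total_params = total,
                 total_params_millions = round(total / 1e6, 2),
                 est_size_mb = estimate_size(total, bytes_per_param),
                 pyramid_dims = NULL,
                 model_name = model_label(model)),
            class = "model_audit")
}

param_shapes <- function(model) {
  if (inherits(model, "pcenet_model")) {
    lapply(model$params, function(p) if (is.null(dim(p))) length(p)
           else dim(p))
  } else if (inherits(model, "model_param_spec")) {
    model$param_dims
  } else if (is.list(model) && !is.null(names(model))) {
    lapply(model, function(p) {
      if (is.numeric(p) && length(p) <= 4L && all(p == round(p)) &&
          is.null(dim(p)) && !is.null(attr(p, "is_shape")))
        as.numeric(p)
      else if (is.null(dim(p))) length(p) else dim(p)
    })
  } else stop("count_parameters: unsupported model object")
}

model_label <- function(model) {
  if (inherits(model, "model_param_spec")) model$name
  else if (inherits(model, "pcenet_model")) {
    if (is.null(model$config$pce)) "residual classifier" else "PCENet"
  } else "parameter list"
}

#' Per-level output dimensions from a live forward pass
#'
#' Probes the model with one input at its configured size and reports
#' the (channels, height, width) of every pyramid level as actually
#' produced, not as configured.
#'
#' @param model A `pcenet_model`.
#' @return Object of class `dimension_table`: a data.frame with columns
#'   `level`, `channels`, `height`, `width`.
#' @export
dimension_table <- function(model) {
  stopifnot(inherits(model, "pcenet_model"))
  sz <- model$arch$input_size
  probe <- array(0, dim = c(sz, sz, 3L, 1L))
  pyr <- model_forward(model, probe, training = FALSE)$pyramid
  tab <- data.frame(
    level = paste0("F", seq_along(pyr)),
    channels = vapply(pyr, function(p) dim(p)[3], 1L),
    height = vapply(pyr, function(p) dim(p)[1], 1L),
    width = vapply(pyr, function(p) dim(p)[2], 1L))
  class(tab) <- c("dimension_table", "data.frame")
  tab
}

#' Estimate serialized model size
#'
#' `total parameters x bytes per parameter / 10^6` megabytes. Reported
#' for 4 bytes (single precision) or 8 bytes (double precision /
#' checkpoint overhead) per parameter.
#'
#' @param audit A `model_audit` or a raw parameter count.
#' @param bytes_per_param 4 or 8.
#' @return Estimated size in MB.
#' @export
#' @examples
#' estimate_size(1e6, 4) # 4.0
estimate_size <- function(audit, bytes_per_param = 4L) {
  if (!bytes_per_param %in% c(4L, 8L))
    stop("estimate_size: bytes_per_param must be 4 or 8")
  total <- if (inherits(audit, "model_audit")) audit$total_params
           else as.numeric(audit)
  total * bytes_per_param / 1e6
}

#' Inference latency harness
#'
#' Times repeated single-batch forward passes (evaluation mode) after
#' discarding warmup runs. Latency is hardware-bound; this harness
#' reports, it does not assert.
#'
#' @param model A `pcenet_model`.
#' @param n_runs Timed runs (>= 1).
#' @param warmup Untimed warmup runs.
#' @param batch Batch size per forward pass.
#' @return Object of class `latency_report`: mean seconds per image,
#'   FPS = 1/mean, run settings and a device descriptor.
#' @export
benchmark_latency <- function(model, n_runs = 10L, warmup = 2L, batch = 1L) {
  stopifnot(inherits(model, "pcenet_model"), n_runs >= 1L)
  sz <- model$arch$input_size
  x <- array(stats::runif(sz * sz * 3 * batch), c(sz, sz, 3L, batch))
  for (i in seq_len(warmup)) model_forward(model, x)
  times <- vapply(seq_len(n_runs), function(i) {
    t0 <- proc.time()[["elapsed"]]
    model_forward(model, x)
    proc.time()[["elapsed"]] - t0
  }, 1)
  mean_s <- mean(times) / batch
  structure(list(mean_seconds_per_image = mean_s,
                 fps = 1 / mean_s,
                 n_runs = n_runs, warmup = warmup, batch = batch,
                 device = paste(R.version$platform, "CPU")),
            class = "latency_report")
}

#' @export
print.model_audit <- function(x, ...) {
  cat("Model audit:", x$model_name, "\n")
  cat(sprintf("  parameters: %s (%.2f M)\n",
              format(x$total_params, big.mark = ","),
              x$total_params_millions))
  cat(sprintf("  est. size:  %.2f MB (4 B/param) / %.2f MB (8 B/param)\n",
              estimate_size(x, 4L), estimate_size(x, 8L)))
  if (!is.null(x$pyramid_dims)) {
    cat("  pyramid:\n")
    print(x$pyramid_dims, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.dimension_table <- function(x, ...) {
  cat("Pyramid dimensions (channels x height x width):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %s: %d x %d x %d\n", x$level[i], x$channels[i],
                x$height[i], x$width[i]))
  invisible(x)
}

#' @export
print.latency_report <- function(x, ...) {
  cat(sprintf(
    "Latency: %.4f s/image (%.1f FPS), %d runs (+%d warmup), batch %d\n",
    x$mean_seconds_per_image, x$fps, x$n_runs, x$warmup, x$batch))
  cat("  device:", x$device, "\n")
  invisible(x)
}

#' Full audit: parameters plus live pyramid dimensions
#'
#' @param model A `pcenet_model`.
#' @param bytes_per_param Bytes per parameter for the size estimate.
#' @return A `model_audit` whose `pyramid_dims` is filled from a live
#'   forward pass.
#' @export
audit_model <- function(model, bytes_per_param = 4L) {
  a <- count_parameters(model, bytes_per_param)
  a$pyramid_dims <- dimension_table(model)
  a
}
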