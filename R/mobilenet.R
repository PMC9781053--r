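# MobileNetV3-Large as a parameter-shape enumeration. The package never
# runs this architecture; it exists so audits can compare PCENet's
# footprint against the standard lightweight baseline at matched class
# counts. Shapes follow the published architecture table (inverted
# residual bottlenecks with optional squeeze-excitation, hard-swish in
# the later stages) and the usual channel-divisibility rule for the
# squeeze width.

make_divisible <- function(v, divisor = 8L) {
  nv <- max(divisor, as.integer(v + divisor / 2) %/% divisor * divisor)
  if (nv < 0.9 * v) nv <- nv + divisor
  as.integer(nv)
}

#' MobileNetV3-Large parameter specification
#'
#' Enumerates every trainable tensor of the standard MobileNetV3-Large
#' classifier with an `n_classes`-way head, for use with
#' [count_parameters()]. Convolutions are bias-free (batch norm
#' follows); the squeeze-excitation convolutions and the classifier
#' linear layers carry biases, matching the reference implementation.
#'
#' @param n_classes Number of output classes.
#' @return Object of class `model_param_spec`.
#' @export
#' @examples
#' count_parameters(mobilenet_v3_large(7))$total_params_millions # 4.21
mobilenet_v3_large <- function(n_classes = 7L) {
  dims <- list()
  add <- function(name, d) dims[[name]] <<- as.numeric(d)
  bn <- function(name, c) {
    add(paste0(name, ".gamma"), c)
    add(paste0(name, ".beta"), c)
  }
  add("stem.W", c(3, 3, 3, 16)); bn("stem.bn", 16)
  # rows: input channels, kernel, expansion, output channels, SE flag
  cfg <- list(
    c(16, 3, 16, 16, 0), c(16, 3, 64, 24, 0), c(24, 3, 72, 24, 0),
    c(24, 5, 72, 40, 1), c(40, 5, 120, 40, 1), c(40, 5, 120, 40, 1),
    c(40, 3, 240, 80, 0), c(80, 3, 200, 80, 0), c(80, 3, 184, 80, 0),
    c(80, 3, 184, 80, 0), c(80, 3, 480, 112, 1), c(112, 3, 672, 112, 1),
    c(112, 5, 672, 160, 1), c(160, 5, 960, 160, 1), c(160, 5, 960, 160, 1))
  for (i in seq_along(cfg)) {
    r <- cfg[[i]]
    cin <- r[1]; k <- r[2]; e <- r[3]; o <- r[4]; se <- r[5]
    p <- sprintf("block%02d.", i)
    if (e != cin) {
      add(paste0(p, "expand.W"), c(1, 1, cin, e)); bn(paste0(p, "expand.bn"), e)
    }
    add(paste0(p, "dw.W"), c(k, k, 1, e)); bn(paste0(p, "dw.bn"), e)
    if (se == 1) {
      sq <- make_divisible(e %/% 4L)
      add(paste0(p, "se.fc1.W"), c(1, 1, e, sq))
      add(paste0(p, "se.fc1.b"), sq)
      add(paste0(p, "se.fc2.W"), c(1, 1, sq, e))
      add(paste0(p, "se.fc2.b"), e)
    }
    add(paste0(p, "project.W"), c(1, 1, e, o)); bn(paste0(p, "project.bn"), o)
  }
  add("conv_last.W", c(1, 1, 160, 960)); bn("conv_last.bn", 960)
  add("classifier.fc1.W", c(960, 1280)); add("classifier.fc1.b", 1280)
  add("classifier.fc2.W", c(1280, n_classes))
  add("classifier.fc2.b", n_classes)
  structure(list(name = "MobileNetV3-Large", param_dims = dims,
                 n_classes = as.integer(n_classes)),
            class = "model_param_spec")
}

#' @export
print.model_param_spec <- function(x, ...) {
  total <- sum(vapply(x$param_dims, prod, 1))
  cat(sprintf("%s parameter spec: %s parameters (%.2f M), %d classes\n",
              x$name, format(total, big.mark = ","), round(total / 1e6, 2),
              x$n_classes))
  invisible(x)
}
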