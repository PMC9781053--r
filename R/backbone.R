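#' Backbone configuration
#'
#' Describes the staged bottleneck residual backbone that emits the
#' feature pyramid F1..F4. Stage output widths are configurable so that
#' pruned variants can be constructed directly; inner bottleneck widths
#' scale proportionally (width = stage width / 4 at the defaults).
#'
#' @param stage_channels Integer vector of stage output widths
#'   (default `c(256, 512, 1024, 2048)`).
#' @param block_counts Number of bottleneck blocks per stage (default
#'   `c(3, 4, 6, 3)`, the 50-layer arrangement).
#' @param input_size Square input size in pixels; must be divisible by
#'   the total spatial stride (32 for four stages).
#' @param n_classes Number of output classes.
#' @return Object of class `backbone_config`.
#' @export
backbone_config <- function(stage_channels = c(256L, 512L, 1024L, 2048L),
                            block_counts = c(3L, 4L, 6L, 3L),
                            input_size = 224L,
                            n_classes = 7L) {
  sc <- as.integer(stage_channels)
  bc <- as.integer(block_counts)
  if (length(sc) != length(bc))
    stop("backbone_config: stage_channels and block_counts lengths differ")
  if (any(sc < 1L) || any(bc < 1L))
    stop("backbone_config: widths and block counts must be positive")
  stride_total <- 4L * 2L^(length(sc) - 1L)
  if (as.integer(input_size) %% stride_total != 0L)
    stop("backbone_config: input_size must be divisible by ", stride_total)
  if (n_classes < 2L)
    stop("backbone_config: need at least 2 classes")
  structure(list(stage_channels = sc, block_counts = bc,
                 input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes)),
            class = "backbone_config")
}

# Explicit per-layer architecture descriptor. Pruning edits these widths
# directly, so a model rebuilt at pruned widths is the same object kind
# as one built from a config.
arch_from_config <- function(cfg) {
  nst <- length(cfg$stage_channels)
  stem <- max(cfg$stage_channels[1L] %/% 4L, 1L)
  stages <- lapply(seq_len(nst), function(i) {
    list(cout = cfg$stage_channels[i],
         stride = if (i == 1L) 1L else 2L,
         blocks = lapply(seq_len(cfg$block_counts[i]), function(j) {
           w <- max(cfg$stage_channels[i] %/% 4L, 1L)
           list(w1 = w, w2 = w)
         }))
  })
  list(type = "resnet", input_size = cfg$input_size,
       n_classes = cfg$n_classes, conv1 = list(cout = stem), stages = stages)
}

kaiming_conv <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

init_from_arch <- function(arch, pce_cfg = NULL) {
  params <- list(); buffers <- list()
  add_bn <- function(name, c) {
    params[[paste0(name, ".gamma")]] <<- rep(1, c)
    params[[paste0(name, ".beta")]] <<- rep(0, c)
    buffers[[paste0(name, ".mean")]] <<- rep(0, c)
    buffers[[paste0(name, ".var")]] <<- rep(1, c)
  }
  if (arch$type == "resnet") {
    params[["conv1.W"]] <- kaiming_conv(7L, 3L, arch$conv1$cout)
    add_bn("bn1", arch$conv1$cout)
    cin <- arch$conv1$cout
    for (i in seq_along(arch$stages)) {
      st <- arch$stages[[i]]
      for (j in seq_along(st$blocks)) {
        w1 <- st$blocks[[j]]$w1
        w2 <- st$blocks[[j]]$w2
        p <- sprintf("s%d.b%d.", i, j)
        params[[paste0(p, "conv1.W")]] <- kaiming_conv(1L, cin, w1)
        add_bn(paste0(p, "bn1"), w1)
        params[[paste0(p, "conv2.W")]] <- kaiming_conv(3L, w1, w2)
        add_bn(paste0(p, "bn2"), w2)
        params[[paste0(p, "conv3.W")]] <- kaiming_conv(1L, w2, st$cout)
        add_bn(paste0(p, "bn3"), st$cout)
        if (j == 1L) {
          params[[paste0(p, "down.W")]] <- kaiming_conv(1L, cin, st$cout)
          add_bn(paste0(p, "dbn"), st$cout)
        }
        cin <- st$cout
      }
    }
    top <- cin
  } else { # seqcnn
    cin <- 3L
    for (i in seq_along(arch$convs)) {
      cv <- arch$convs[[i]]
      params[[sprintf("c%d.W", i)]] <- kaiming_conv(cv$k, cin, cv$cout)
      add_bn(sprintf("bn%d", i), cv$cout)
      cin <- cv$cout
    }
    top <- cin
  }
  if (!is.null(pce_cfg)) {
    pp <- init_pce_params(pce_cfg)
    for (l in seq_along(pp$levels)) {
      for (nm in names(pp$levels[[l]])) {
        params[[sprintf("pce.l%d.%s.W", l, nm)]] <- pp$levels[[l]][[nm]]$W
        params[[sprintf("pce.l%d.%s.b", l, nm)]] <- pp$levels[[l]][[nm]]$b
      }
    }
    params[["pce.attn.W"]] <- pp$attn$W
    params[["pce.attn.b"]] <- pp$attn$b
  }
  lim <- 1 / sqrt(top)
  params[["head.W"]] <- matrix(stats::runif(top * arch$n_classes, -lim, lim),
                               top, arch$n_classes)
  params[["head.b"]] <- rep(0, arch$n_classes)
  list(params = params, buffers = buffers)
}

build_from_arch <- function(arch, pce_cfg = NULL, seed = NULL) {
  run <- function() init_from_arch(arch, pce_cfg)
  pb <- if (is.null(seed)) run() else with_preserved_seed(seed, run())
  structure(list(arch = arch, params = pb$params, buffers = pb$buffers,
                 config = list(pce = pce_cfg, n_classes = arch$n_classes)),
            class = "pcenet_model")
}

#' Build a PCENet (or plain residual) classifier
#'
#' Constructs the staged bottleneck backbone and, when a PCE
#' configuration is given, the contextual attention module over its
#' feature pyramid plus a linear classification head on the attended,
#' globally pooled top representation. With `pce_cfg = NULL` the result
#' is a plain residual classifier (the 50-layer default reproduces the
#' standard ResNet50 parameterization).
#'
#' @param backbone_cfg A [backbone_config()].
#' @param pce_cfg A [pce_config()] whose `level_channels` equal the
#'   backbone's `stage_channels`, or `NULL` for no attention module.
#' @param seed Optional integer seed; the same seed yields bitwise
#'   identical initial weights.
#' @return Object of class `pcenet_model`.
#' @export
#' @examples
#' m <- build_model(backbone_config(c(4, 8, 16, 32), c(1, 1, 1, 1),
#'                                  input_size = 64, n_classes = 3),
#'                  seed = 1)
build_model <- function(backbone_cfg, pce_cfg = NULL, seed = NULL) {
  stopifnot(inherits(backbone_cfg, "backbone_config"))
  if (!is.null(pce_cfg)) {
    stopifnot(inherits(pce_cfg, "pce_config"))
    if (!identical(as.integer(pce_cfg$level_channels),
                   as.integer(backbone_cfg$stage_channels)))
      stop("build_model: pce level_channels (",
           paste(pce_cfg$level_channels, collapse = ","),
           ") must equal backbone stage_channels (",
           paste(backbone_cfg$stage_channels, collapse = ","), ")")
  }
  build_from_arch(arch_from_config(backbone_cfg), pce_cfg, seed)
}

#' Standard 50-layer residual classifier
#'
#' Convenience wrapper building the plain bottleneck residual network
#' (no attention module) at the standard widths.
#'
#' @param n_classes Number of classes.
#' @param seed Optional seed for the weight draw.
#' @return A `pcenet_model` without a PCE module.
#' @export
resnet50_classifier <- function(n_classes = 7L, seed = NULL) {
  build_model(backbone_config(n_classes = n_classes), pce_cfg = NULL,
              seed = seed)
}

#' Build a PCENet with default or scaled settings
#'
#' @param stage_channels Stage output widths.
#' @param block_counts Blocks per stage.
#' @param input_size Input size in pixels.
#' @param n_classes Number of classes.
#' @param reduction_ratio PCE reduction ratio.
#' @param seed Optional seed.
#' @return A `pcenet_model` with the PCE module attached.
#' @export
pcenet_classifier <- function(stage_channels = c(256L, 512L, 1024L, 2048L),
                              block_counts = c(3L, 4L, 6L, 3L),
                              input_size = 224L, n_classes = 7L,
                              reduction_ratio = 16L, seed = NULL) {
  bc <- backbone_config(stage_channels, block_counts, input_size, n_classes)
  pc <- pce_config(reduction_ratio = reduction_ratio,
                   top_channels = stage_channels[length(stage_channels)],
                   level_channels = stage_channels)
  build_model(bc, pc, seed)
}

# Reassemble the structured PCE parameter view from the flat list.
view_pce_params <- function(model) {
  cfg <- model$config$pce
  nlev <- length(cfg$level_channels) - 1L
  p <- model$params
  levels <- lapply(seq_len(nlev), function(l) {
    nm <- c("fi", "mi", "fo", "mo", "fs", "ms")
    stats::setNames(lapply(nm, function(g) {
      list(W = p[[sprintf("pce.l%d.%s.W", l, g)]],
           b = p[[sprintf("pce.l%d.%s.b", l, g)]])
    }), nm)
  })
  structure(list(levels = levels,
                 attn = list(W = p[["pce.attn.W"]], b = p[["pce.attn.b"]]),
                 config = cfg),
            class = "pce_params")
}

bn_apply <- function(st, x, name, training) {
  r <- op_bn_fwd(x, st$params[[paste0(name, ".gamma")]],
                 st$params[[paste0(name, ".beta")]],
                 st$buffers[[paste0(name, ".mean")]],
                 st$buffers[[paste0(name, ".var")]], training)
  if (training) {
    st$buffers[[paste0(name, ".mean")]] <- r$run_mean
    st$buffers[[paste0(name, ".var")]] <- r$run_var
  }
  r
}

block_fwd <- function(st, x, i, j, stride, training) {
  p <- sprintf("s%d.b%d.", i, j)
  c1 <- op_conv_fwd(x, st$params[[paste0(p, "conv1.W")]], 1L, 0L)
  b1 <- bn_apply(st, c1$out, paste0(p, "bn1"), training)
  r1 <- op_relu_fwd(b1$out)
  c2 <- op_conv_fwd(r1$out, st$params[[paste0(p, "conv2.W")]], stride, 1L)
  b2 <- bn_apply(st, c2$out, paste0(p, "bn2"), training)
  r2 <- op_relu_fwd(b2$out)
  c3 <- op_conv_fwd(r2$out, st$params[[paste0(p, "conv3.W")]], 1L, 0L)
  b3 <- bn_apply(st, c3$out, paste0(p, "bn3"), training)
  if (j == 1L) {
    cd <- op_conv_fwd(x, st$params[[paste0(p, "down.W")]], stride, 0L)
    bd <- bn_apply(st, cd$out, paste0(p, "dbn"), training)
    short <- bd$out
  } else {
    cd <- NULL; bd <- NULL
    short <- x
  }
  ro <- op_relu_fwd(b3$out + short)
  list(out = ro$out,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
                    c3 = c3$cache, b3 = b3$cache,
                    cd = if (is.null(cd)) NULL else cd$cache,
                    bd = if (is.null(bd)) NULL else bd$cache,
                    ro = ro$cache))
}

block_bwd <- function(st, dy, i, j, cache) {
  p <- sprintf("s%d.b%d.", i, j)
  g <- st$grads
  d3 <- op_relu_bwd(dy, cache$ro)
  # main branch
  gb3 <- op_bn_bwd(d3, cache$b3)
  g[[paste0(p, "bn3.gamma")]] <- gb3$dgamma
  g[[paste0(p, "bn3.beta")]] <- gb3$dbeta
  gc3 <- op_conv_bwd(gb3$dx, cache$c3)
  g[[paste0(p, "conv3.W")]] <- gc3$dW
  dr2 <- op_relu_bwd(gc3$dx, cache$r2)
  gb2 <- op_bn_bwd(dr2, cache$b2)
  g[[paste0(p, "bn2.gamma")]] <- gb2$dgamma
  g[[paste0(p, "bn2.beta")]] <- gb2$dbeta
  gc2 <- op_conv_bwd(gb2$dx, cache$c2)
  g[[paste0(p, "conv2.W")]] <- gc2$dW
  dr1 <- op_relu_bwd(gc2$dx, cache$r1)
  gb1 <- op_bn_bwd(dr1, cache$b1)
  g[[paste0(p, "bn1.gamma")]] <- gb1$dgamma
  g[[paste0(p, "bn1.beta")]] <- gb1$dbeta
  gc1 <- op_conv_bwd(gb1$dx, cache$c1)
  g[[paste0(p, "conv1.W")]] <- gc1$dW
  dx <- gc1$dx
  # shortcut
  if (!is.null(cache$cd)) {
    gbd <- op_bn_bwd(d3, cache$bd)
    g[[paste0(p, "dbn.gamma")]] <- gbd$dgamma
    g[[paste0(p, "dbn.beta")]] <- gbd$dbeta
    gcd <- op_conv_bwd(gbd$dx, cache$cd)
    g[[paste0(p, "down.W")]] <- gcd$dW
    dx <- dx + gcd$dx
  } else {
    dx <- dx + d3
  }
  st$grads <- g
  dx
}

# Full forward pass. `st` is an environment holding params/buffers so
# that batch-norm running statistics can be updated in place during
# training. Returns logits, the feature pyramid, and (optionally) the
# caches needed by model_backward.
model_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  d <- dim(x)
  if (length(d) != 4L)
    stop("model_forward: expected an (H, W, C, N) array")
  if (d[1] != model$arch$input_size || d[2] != model$arch$input_size)
    stop("model_forward: input is ", d[1], "x", d[2],
         " but the model expects ", model$arch$input_size, "x",
         model$arch$input_size)
  if (d[3] != 3L) stop("model_forward: expected 3 input channels")
  st <- new.env(parent = emptyenv())
  st$params <- model$params
  st$buffers <- model$buffers
  arch <- model$arch
  cache <- list()
  pyramid <- list()
  if (arch$type == "resnet") {
    c1 <- op_conv_fwd(x, st$params[["conv1.W"]], 2L, 3L)
    b1 <- bn_apply(st, c1$out, "bn1", training)
    r1 <- op_relu_fwd(b1$out)
    mp <- op_maxpool_fwd(r1$out)
    cache$stem <- list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                       mp = mp$cache)
    h <- mp$out
    cache$stages <- vector("list", length(arch$stages))
    for (i in seq_along(arch$stages)) {
      stg <- arch$stages[[i]]
      bl <- vector("list", length(stg$blocks))
      for (j in seq_along(stg$blocks)) {
        r <- block_fwd(st, h, i, j, if (j == 1L) stg$stride else 1L, training)
        h <- r$out
        bl[[j]] <- r$cache
      }
      cache$stages[[i]] <- bl
      pyramid[[i]] <- h
    }
  } else {
    h <- x
    cache$convs <- vector("list", length(arch$convs))
    for (i in seq_along(arch$convs)) {
      cv <- arch$convs[[i]]
      cc <- op_conv_fwd(h, st$params[[sprintf("c%d.W", i)]], cv$stride,
                        cv$pad)
      bb <- bn_apply(st, cc$out, sprintf("bn%d", i), training)
      rr <- op_relu_fwd(bb$out)
      cache$convs[[i]] <- list(c = cc$cache, b = bb$cache, r = rr$cache)
      h <- rr$out
      pyramid[[i]] <- h
    }
  }
  top <- pyramid[[length(pyramid)]]
  if (!is.null(model$config$pce)) {
    pp <- view_pce_params(model)
    nlev <- length(pp$levels)
    gaps <- lapply(seq_len(nlev), function(l) op_gap_fwd(pyramid[[l]]))
    ch <- pce_chain_fwd(lapply(gaps, `[[`, "out"), pp)
    at <- op_linear_fwd(ch$m, pp$attn$W, pp$attn$b)
    sc <- op_scale_fwd(top, at$out)
    cache$pce <- list(gaps = lapply(gaps, `[[`, "cache"),
                      chain = ch$caches, attn = at$cache, scale = sc$cache)
    top <- sc$out
  }
  gp <- op_gap_fwd(top)
  hd <- op_linear_fwd(gp$out, st$params[["head.W"]], st$params[["head.b"]])
  cache$gap <- gp$cache
  cache$head <- hd$cache
  list(logits = hd$out, pyramid = pyramid,
       cache = if (keep_cache) cache else NULL,
       buffers = st$buffers)
}

# Backward pass; returns the named gradient list (same names as params).
model_backward <- function(model, cache, dlogits) {
  st <- new.env(parent = emptyenv())
  st$params <- model$params
  st$grads <- list()
  arch <- model$arch
  gh <- op_linear_bwd(dlogits, cache$head)
  st$grads[["head.W"]] <- gh$dW
  st$grads[["head.b"]] <- gh$db
  dtop <- op_gap_bwd(gh$dx, cache$gap)
  nlev_total <- if (arch$type == "resnet") length(arch$stages)
                else length(arch$convs)
  dpyr <- vector("list", nlev_total)
  if (!is.null(model$config$pce)) {
    pp <- view_pce_params(model)
    sb <- op_scale_bwd(dtop, cache$pce$scale)
    dtop <- sb$dx
    ga <- op_linear_bwd(sb$dv, cache$pce$attn)
    st$grads[["pce.attn.W"]] <- ga$dW
    st$grads[["pce.attn.b"]] <- ga$db
    cb <- pce_chain_bwd(ga$dx, cache$pce$chain, pp)
    for (l in seq_along(cb$level_grads)) {
      for (g in names(cb$level_grads[[l]])) {
        st$grads[[sprintf("pce.l%d.%s.W", l, g)]] <- cb$level_grads[[l]][[g]]$W
        st$grads[[sprintf("pce.l%d.%s.b", l, g)]] <- cb$level_grads[[l]][[g]]$b
      }
      dpyr[[l]] <- op_gap_bwd(cb$dfs[[l]], cache$pce$gaps[[l]])
    }
  }
  dpyr[[nlev_total]] <- if (is.null(dpyr[[nlev_total]])) dtop
                        else dpyr[[nlev_total]] + dtop
  if (arch$type == "resnet") {
    dh <- NULL
    for (i in rev(seq_along(arch$stages))) {
      dh <- if (is.null(dh)) dpyr[[i]]
            else if (is.null(dpyr[[i]])) dh else dh + dpyr[[i]]
      for (j in rev(seq_along(arch$stages[[i]]$blocks)))
        dh <- block_bwd(st, dh, i, j, cache$stages[[i]][[j]])
    }
    dmp <- op_maxpool_bwd(dh, cache$stem$mp)
    dr1 <- op_relu_bwd(dmp, cache$stem$r1)
    gb1 <- op_bn_bwd(dr1, cache$stem$b1)
    st$grads[["bn1.gamma"]] <- gb1$dgamma
    st$grads[["bn1.beta"]] <- gb1$dbeta
    gc1 <- op_conv_bwd(gb1$dx, cache$stem$c1)
    st$grads[["conv1.W"]] <- gc1$dW
  } else {
    dh <- NULL
    for (i in rev(seq_along(arch$convs))) {
      dh <- if (is.null(dh)) dpyr[[i]]
            else if (is.null(dpyr[[i]])) dh else dh + dpyr[[i]]
      cc <- cache$convs[[i]]
      dr <- op_relu_bwd(dh, cc$r)
      gb <- op_bn_bwd(dr, cc$b)
      st$grads[[sprintf("bn%d.gamma", i)]] <- gb$dgamma
      st$grads[[sprintf("bn%d.beta", i)]] <- gb$dbeta
      gc <- op_conv_bwd(gb$dx, cc$c)
      st$grads[[sprintf("c%d.W", i)]] <- gc$dW
      dh <- gc$dx
    }
  }
  st$grads
}

#' Forward pass returning the feature pyramid and logits
#'
#' Runs the model in evaluation mode (batch-norm uses running
#' statistics) on a batch of images.
#'
#' @param model A `pcenet_model`.
#' @param x An (H, W, 3, N) array of images at the model's input size,
#'   or a single (H, W, 3) image.
#' @return `list(pyramid, logits)`: the per-stage representations (each
#'   an (H, W, C, N) array) and the N x n_classes logit matrix.
#' @export
forward_features <- function(model, x) {
  stopifnot(inherits(model, "pcenet_model"))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  r <- model_forward(model, x, training = FALSE)
  list(pyramid = r$pyramid, logits = r$logits)
}

#' Predict classes or probabilities
#'
#' @param object A `pcenet_model`.
#' @param newdata A [labeled_image_set()] or an (H, W, 3, N) array.
#' @param type `"class"` (0-based integer labels), `"prob"` or
#'   `"logits"`.
#' @param batch_size Evaluation batch size.
#' @param ... Unused.
#' @return Predicted labels, probability matrix, or logits.
#' @export
predict.pcenet_model <- function(object, newdata, type = c("class", "prob",
                                                           "logits"),
                                 batch_size = 32L, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "labeled_image_set"))
    resize_images(newdata$images, object$arch$input_size) else newdata
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[4]
  out <- matrix(0, n, object$arch$n_classes)
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    out[ix, ] <- model_forward(object, x[, , , ix, drop = FALSE])$logits
  }
  switch(type,
         logits = out,
         prob = {
           e <- exp(out - apply(out, 1, max)); e / rowSums(e)
         },
         class = max.col(out, ties.method = "first") - 1L)
}

#' @export
print.pcenet_model <- function(x, ...) {
  a <- count_parameters(x)
  cat(if (is.null(x$config$pce)) "Residual classifier" else
    "PCENet classifier", "\n")
  if (x$arch$type == "resnet") {
    cat("  stages:      ",
        paste(vapply(x$arch$stages, function(s) s$cout, 1L), collapse = "/"),
        " (blocks ",
        paste(vapply(x$arch$stages, function(s) length(s$blocks), 1L),
              collapse = "/"), ")\n", sep = "")
  } else {
    cat("  convs:       ",
        paste(vapply(x$arch$convs, function(s) s$cout, 1L), collapse = "/"),
        "\n", sep = "")
  }
  cat("  input size:  ", x$arch$input_size, "\n")
  cat("  classes:     ", x$arch$n_classes, "\n")
  cat("  parameters:  ", format(a$total_params, big.mark = ","),
      sprintf(" (%.2f M)\n", a$total_params_millions))
  invisible(x)
}

# Plain sequential CNN (conv-bn-relu chain + linear head); used for
# small single-path models in tests and as a pruning testbed.
#' Build a small sequential CNN classifier
#'
#' A single-path convolutional classifier (conv + batch-norm + ReLU
#' chain, global average pooling, linear head). Useful as a compact
#' testbed: its pruning behaviour has no residual coupling.
#'
#' @param widths Output channels of each convolution.
#' @param strides Stride per convolution (default 2 everywhere).
#' @param kernel Kernel size (default 3).
#' @param input_size Square input size.
#' @param n_classes Number of classes.
#' @param seed Optional seed.
#' @return A `pcenet_model` with `arch$type == "seqcnn"`.
#' @export
seq_cnn_classifier <- function(widths, strides = rep(2L, length(widths)),
                               kernel = 3L, input_size = 32L,
                               n_classes = 2L, seed = NULL) {
  stopifnot(length(widths) == length(strides), all(widths >= 1L))
  arch <- list(type = "seqcnn", input_size = as.integer(input_size),
               n_classes = as.integer(n_classes),
               convs = lapply(seq_along(widths), function(i) {
                 list(cout = as.integer(widths[i]), k = as.integer(kernel),
                      stride = as.integer(strides[i]),
                      pad = as.integer(kernel %/% 2L))
               }))
  build_from_arch(arch, NULL, seed)
}
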