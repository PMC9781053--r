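# Internal forward/backward primitives for the CNN engine.
#
# Activations are numeric arrays with dim (H, W, C, N); convolution
# weights have dim (kh, kw, Cin, Cout); fully connected layers follow
# the row-vector convention y = x W + b (W is in x out), so a batch is
# an N x in matrix. Each *_fwd returns list(out, cache); the matching
# *_bwd consumes the cache and returns gradients.

op_conv_fwd <- function(x, W, stride, pad) {
  out <- .conv2d_fwd(x, W, as.integer(stride), as.integer(pad))
  list(out = out, cache = list(x = x, W = W, stride = stride, pad = pad))
}

op_conv_bwd <- function(dout, cache) {
  g <- .conv2d_bwd(cache$x, cache$W, dout,
                   as.integer(cache$stride), as.integer(cache$pad))
  list(dx = g$dx, dW = g$dw)
}

op_maxpool_fwd <- function(x, k = 3L, stride = 2L, pad = 1L) {
  r <- .maxpool_fwd(x, as.integer(k), as.integer(stride), as.integer(pad))
  list(out = r$out, cache = list(argmax = r$argmax, xdim = dim(x)))
}

op_maxpool_bwd <- function(dout, cache) {
  .maxpool_bwd(dout, cache$argmax, as.integer(cache$xdim))
}

op_relu_fwd <- function(x) {
  out <- x * (x > 0)
  list(out = out, cache = x > 0)
}

op_relu_bwd <- function(dout, cache) dout * cache

# Batch normalization over (H, W, N) per channel. The (H, W, C, N)
# array is viewed as an (H*W) x (C*N) matrix whose column index factors
# as (channel, sample), so per-channel moments come from colMeans
# without transposing the data.
op_bn_fwd <- function(x, gamma, beta, run_mean, run_var,
                      training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  xm <- matrix(x, nrow = hw)
  if (training) {
    cm <- matrix(colMeans(xm), C, N)
    mu <- rowMeans(cm)
    cm2 <- matrix(colMeans(xm * xm), C, N)
    v <- rowMeans(cm2) - mu^2            # biased variance, as used to normalize
    m <- hw * N
    new_mean <- (1 - momentum) * run_mean + momentum * mu
    new_var <- (1 - momentum) * run_var + momentum * v * m / max(m - 1, 1)
  } else {
    mu <- run_mean; v <- run_var
    new_mean <- run_mean; new_var <- run_var
  }
  inv <- 1 / sqrt(v + eps)
  mu_e <- rep(mu, times = N); inv_e <- rep(inv, times = N)
  xhat <- (xm - matrix(mu_e, hw, C * N, byrow = TRUE)) *
    matrix(inv_e, hw, C * N, byrow = TRUE)
  g_e <- rep(gamma, times = N); b_e <- rep(beta, times = N)
  out <- xhat * matrix(g_e, hw, C * N, byrow = TRUE) +
    matrix(b_e, hw, C * N, byrow = TRUE)
  dim(out) <- d
  list(out = out,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d,
                    training = training),
       run_mean = new_mean, run_var = new_var)
}

op_bn_bwd <- function(dout, cache) {
  d <- cache$d
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  dm <- matrix(dout, nrow = hw)
  xhat <- cache$xhat
  per_col_sum <- function(m) matrix(colSums(m), C, N)
  dgamma <- rowSums(per_col_sum(dm * xhat))
  dbeta <- rowSums(per_col_sum(dm))
  g_e <- matrix(rep(cache$gamma, times = N), hw, C * N, byrow = TRUE)
  dxhat <- dm * g_e
  if (cache$training) {
    m <- hw * N
    s1 <- rep(rowSums(per_col_sum(dxhat)), times = N)
    s2 <- rep(rowSums(per_col_sum(dxhat * xhat)), times = N)
    dx <- (dxhat - matrix(s1, hw, C * N, byrow = TRUE) / m -
             xhat * matrix(s2, hw, C * N, byrow = TRUE) / m) *
      matrix(rep(cache$inv, times = N), hw, C * N, byrow = TRUE)
  } else {
    dx <- dxhat * matrix(rep(cache$inv, times = N), hw, C * N, byrow = TRUE)
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Global average pooling to an N x C matrix of channel statistics.
op_gap_fwd <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  out <- t(matrix(colMeans(matrix(x, nrow = hw)), d[3], d[4]))
  list(out = out, cache = d)
}

op_gap_bwd <- function(dout, cache) {
  d <- cache
  hw <- d[1] * d[2]
  dx <- matrix(rep(as.numeric(t(dout)) / hw, each = hw), nrow = hw)
  dim(dx) <- d
  dx
}

op_linear_fwd <- function(x, W, b) {
  out <- x %*% W + matrix(b, nrow(x), length(b), byrow = TRUE)
  list(out = out, cache = list(x = x, W = W))
}

op_linear_bwd <- function(dout, cache) {
  list(dx = dout %*% t(cache$W),
       dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

# Per-channel scaling of a (H, W, C, N) map by an N x C matrix.
op_scale_fwd <- function(x, v) {
  d <- dim(x)
  hw <- d[1] * d[2]
  ve <- matrix(rep(as.numeric(t(v)), each = hw), hw, d[3] * d[4])
  xm <- matrix(x, nrow = hw)
  out <- xm * ve
  dim(out) <- d
  list(out = out, cache = list(xm = xm, ve = ve, d = d))
}

op_scale_bwd <- function(dout, cache) {
  d <- cache$d
  hw <- d[1] * d[2]
  dm <- matrix(dout, nrow = hw)
  dx <- dm * cache$ve
  dim(dx) <- d
  dv <- t(matrix(colSums(dm * cache$xm), d[3], d[4]))
  list(dx = dx, dv = dv)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Softmax cross-entropy on an N x K logit matrix; labels are 0-based.
op_softmax_ce <- function(logits, labels) {
  n <- nrow(logits)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  p <- ex / rowSums(ex)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, prob = p)
}
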