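#' Configuration of the progressive contextual excitation (PCE) module
#'
#' The PCE module summarizes each level of a backbone's feature pyramid by
#' global average pooling, accumulates the per-level channel statistics
#' with a gated memory cell into a contextual cue, and projects the final
#' cue to a per-channel attention vector that re-weights the top-level
#' representation. The memory width is the top channel count divided by
#' the reduction ratio (2048 / 16 = 128 by default).
#'
#' @param reduction_ratio Positive integer divisor of `top_channels`
#'   shrinking the memory bottleneck (default 16).
#' @param top_channels Channel count of the attended top level (default
#'   2048).
#' @param level_channels Integer vector of per-level channel counts,
#'   lowest level first; the last entry must equal `top_channels`.
#' @param memory_dim Width of the memory state; defaults to
#'   `top_channels / reduction_ratio`. Overriding it is only meant for
#'   internal reconstruction of pruned models, where the memory width is
#'   deliberately kept at its pre-pruning value.
#' @return An object of class `pce_config`.
#' @export
#' @examples
#' cfg <- pce_config()
#' cfg$memory_dim # 128
pce_config <- function(reduction_ratio = 16L,
                       top_channels = 2048L,
                       level_channels = c(256L, 512L, 1024L, 2048L),
                       memory_dim = NULL) {
  r <- as.integer(reduction_ratio)
  c4 <- as.integer(top_channels)
  lc <- as.integer(level_channels)
  if (r < 1L || c4 < 1L || any(lc < 1L))
    stop("pce_config: all dimensions must be positive integers")
  if (length(lc) < 2L)
    stop("pce_config: need at least two pyramid levels")
  if (lc[length(lc)] != c4)
    stop("pce_config: last level_channels entry (", lc[length(lc)],
         ") must equal top_channels (", c4, ")")
  if (is.null(memory_dim)) {
    if (c4 %% r != 0L)
      stop("pce_config: top_channels (", c4,
           ") must be divisible by reduction_ratio (", r, ")")
    memory_dim <- c4 %/% r
  }
  structure(list(reduction_ratio = r, top_channels = c4,
                 level_channels = lc,
                 memory_dim = as.integer(memory_dim)),
            class = "pce_config")
}

#' Affine projection of a feature vector
#'
#' The elementary linear transform used throughout the PCE module:
#' `x W + b` with `x` a row vector.
#'
#' @param x Numeric vector of length `nrow(W)`.
#' @param W Projection matrix (input dim x output dim).
#' @param b Bias vector of length `ncol(W)`.
#' @return Numeric vector `x W + b` of length `ncol(W)`.
#' @export
#' @examples
#' linear_transform(c(1, 2), matrix(c(1, 1, 0, 1), 2, 2), c(1, 1)) # 4 3
linear_transform <- function(x, W, b) {
  if (length(x) != nrow(W))
    stop("linear_transform: x has length ", length(x),
         " but W is ", nrow(W), " x ", ncol(W))
  if (length(b) != ncol(W))
    stop("linear_transform: b has length ", length(b),
         " but W is ", nrow(W), " x ", ncol(W))
  drop(matrix(x, 1L) %*% W) + b
}

#' Channel-wise statistics by global average pooling
#'
#' Reduces one pyramid level to its per-channel spatial mean.
#'
#' @param f A rank-3 array laid out (height, width, channels).
#' @return Numeric vector of per-channel means, length `dim(f)[3]`.
#' @export
global_average_pool <- function(f) {
  d <- dim(f)
  if (length(d) != 3L)
    stop("global_average_pool: expected a rank-3 (h, w, c) array")
  if (d[1] < 1L || d[2] < 1L)
    stop("global_average_pool: empty spatial extent")
  colMeans(matrix(f, nrow = d[1] * d[2]))
}

#' Create a memory state
#'
#' @param m Numeric state vector.
#' @param level Pyramid level that produced it (0 = initial state).
#' @return Object of class `memory_state`.
#' @export
memory_state <- function(m, level = 0L) {
  if (!all(is.finite(m))) stop("memory_state: entries must be finite")
  structure(list(m = as.numeric(m), level = as.integer(level)),
            class = "memory_state")
}

#' Initialize PCE parameters
#'
#' Each memory level owns three input-side projections (channel
#' statistics to memory width, one per gate/candidate) and three
#' memory-side projections (memory width to memory width); one final
#' projection maps the memory to the attention vector over the top
#' channels. All are independent (W, b) pairs: the input and output
#' gates deliberately do not share weights, otherwise their printed
#' defining equations would collapse into one gate.
#'
#' @param cfg A [pce_config()].
#' @param seed Optional integer seed making the draw reproducible.
#' @return Object of class `pce_params`: `$levels[[l]]` holds
#'   projections `fi, mi, fo, mo, fs, ms` (each `list(W, b)`), and
#'   `$attn` the attention projection.
#' @export
init_pce_params <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "pce_config"))
  run <- function() {
    d <- cfg$memory_dim
    lin <- function(nin, nout) {
      lim <- 1 / sqrt(nin)
      list(W = matrix(stats::runif(nin * nout, -lim, lim), nin, nout),
           b = stats::runif(nout, -lim, lim))
    }
    nlev <- length(cfg$level_channels) - 1L
    levels <- lapply(seq_len(nlev), function(l) {
      cl <- cfg$level_channels[l]
      list(fi = lin(cl, d), mi = lin(d, d),
           fo = lin(cl, d), mo = lin(d, d),
           fs = lin(cl, d), ms = lin(d, d))
    })
    structure(list(levels = levels, attn = lin(d, cfg$top_channels),
                   config = cfg),
              class = "pce_params")
  }
  if (is.null(seed)) run() else with_preserved_seed(seed, run())
}

# Evaluate seed-dependent code without disturbing the caller's RNG.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' One step of the contextual memory cell
#'
#' Updates the memorized cue from one level's channel statistics:
#' \deqn{i = \sigma(\phi(f) + \phi(m)),\quad o = \sigma(\phi(f) + \phi(m)),}
#' \deqn{s = \tanh(\phi(f) + \phi(i \odot m)),\quad
#'       m' = o \odot m + (1 - o) \odot s,}
#' with every \eqn{\phi} its own affine projection and all products
#' element-wise. Note the candidate feeds the gated memory through a
#' projection and the update mixes the old memory with the candidate
#' through `o`; this is the cell as defined for PCE, not a standard
#' LSTM cell.
#'
#' @param f_l Channel statistics vector for level `level`.
#' @param m_prev Previous [memory_state()] (or plain numeric vector).
#' @param params [init_pce_params()] object.
#' @param level Level index in `1..(n_levels - 1)`.
#' @return The updated [memory_state()].
#' @export
memory_step <- function(f_l, m_prev, params, level) {
  stopifnot(inherits(params, "pce_params"))
  cfg <- params$config
  if (level < 1L || level > length(params$levels))
    stop("memory_step: level must be in 1..", length(params$levels))
  if (length(f_l) != cfg$level_channels[level])
    stop("memory_step: f_l has length ", length(f_l), " but level ",
         level, " expects ", cfg$level_channels[level])
  m <- if (inherits(m_prev, "memory_state")) m_prev$m else as.numeric(m_prev)
  if (length(m) != cfg$memory_dim)
    stop("memory_step: memory has length ", length(m),
         " but memory_dim is ", cfg$memory_dim)
  r <- pce_cell_fwd(matrix(f_l, 1L), matrix(m, 1L), params$levels[[level]])
  out <- drop(r$m)
  if (!all(is.finite(out))) stop("memory_step: non-finite memory state")
  memory_state(out, level)
}

# Batched memory cell: f (N x c_l), m (N x d). Returns the new memory
# plus everything the backward pass needs.
pce_cell_fwd <- function(f, m, p) {
  lin <- function(x, pr) x %*% pr$W +
    matrix(pr$b, nrow(x), length(pr$b), byrow = TRUE)
  i <- sigmoid(lin(f, p$fi) + lin(m, p$mi))
  o <- sigmoid(lin(f, p$fo) + lin(m, p$mo))
  q <- i * m
  s <- tanh(lin(f, p$fs) + lin(q, p$ms))
  list(m = o * m + (1 - o) * s,
       cache = list(f = f, m = m, i = i, o = o, q = q, s = s))
}

pce_cell_bwd <- function(dm_new, cache, p) {
  f <- cache$f; m <- cache$m
  i <- cache$i; o <- cache$o; s <- cache$s
  do <- dm_new * (m - s)
  ds <- dm_new * (1 - o)
  dm <- dm_new * o
  ds_pre <- ds * (1 - s * s)
  dq <- ds_pre %*% t(p$ms$W)
  di <- dq * m
  dm <- dm + dq * i
  di_pre <- di * i * (1 - i)
  do_pre <- do * o * (1 - o)
  df <- di_pre %*% t(p$fi$W) + do_pre %*% t(p$fo$W) + ds_pre %*% t(p$fs$W)
  dm <- dm + di_pre %*% t(p$mi$W) + do_pre %*% t(p$mo$W)
  gr <- function(x, dpre) list(W = crossprod(x, dpre), b = colSums(dpre))
  list(df = df, dm = dm,
       grads = list(fi = gr(f, di_pre), mi = gr(m, di_pre),
                    fo = gr(f, do_pre), mo = gr(m, do_pre),
                    fs = gr(f, ds_pre), ms = gr(cache$q, ds_pre)))
}

#' Run the memory chain over a feature pyramid
#'
#' Pools every level below the top one and folds its channel statistics
#' into the memory cell, starting from the zero initial state, yielding
#' the final contextual cue (`m3` for the default four-level pyramid).
#'
#' @param pyramid List of rank-3 (h, w, c) arrays, lowest level first.
#'   Only the levels below the top feed the memory; a pyramid may
#'   include the top level (it is ignored here) or omit it.
#' @param params [init_pce_params()] object.
#' @return The final [memory_state()].
#' @export
run_memory_chain <- function(pyramid, params) {
  stopifnot(inherits(params, "pce_params"))
  cfg <- params$config
  nlev <- length(params$levels)
  if (length(pyramid) < nlev)
    stop("run_memory_chain: pyramid has ", length(pyramid),
         " levels; need at least ", nlev)
  state <- memory_state(numeric(cfg$memory_dim), 0L)
  for (l in seq_len(nlev))
    state <- memory_step(global_average_pool(pyramid[[l]]), state, params, l)
  state
}

#' Contextual channel attention from the final memory state
#'
#' Projects the contextual cue to one scaling weight per top-level
#' channel: `v = phi(m)`.
#'
#' @param m3 Final [memory_state()] (or plain numeric vector).
#' @param params [init_pce_params()] object.
#' @return Numeric attention vector of length `top_channels`.
#' @export
contextual_attention <- function(m3, params) {
  stopifnot(inherits(params, "pce_params"))
  m <- if (inherits(m3, "memory_state")) m3$m else as.numeric(m3)
  linear_transform(m, params$attn$W, params$attn$b)
}

#' Apply channel attention to the top-level representation
#'
#' Scales every spatial value of channel j by `v[j]`.
#'
#' @param f4 Rank-3 (h, w, c) array, the top pyramid level.
#' @param v Attention vector of length `dim(f4)[3]`.
#' @return The attended representation, same shape as `f4`.
#' @export
apply_attention <- function(f4, v) {
  d <- dim(f4)
  if (length(d) != 3L)
    stop("apply_attention: expected a rank-3 (h, w, c) array")
  if (length(v) != d[3])
    stop("apply_attention: v has length ", length(v), " but f4 has ",
         d[3], " channels")
  out <- matrix(f4, nrow = d[1] * d[2]) *
    matrix(v, d[1] * d[2], d[3], byrow = TRUE)
  dim(out) <- d
  out
}

# ---- batched chain used inside the model forward/backward ----

# fs: list of N x c_l channel-statistic matrices for levels 1..nlev.
pce_chain_fwd <- function(fs, params) {
  n <- nrow(fs[[1L]])
  m <- matrix(0, n, params$config$memory_dim)
  caches <- vector("list", length(fs))
  for (l in seq_along(fs)) {
    r <- pce_cell_fwd(fs[[l]], m, params$levels[[l]])
    m <- r$m
    caches[[l]] <- r$cache
  }
  list(m = m, caches = caches)
}

pce_chain_bwd <- function(dm, caches, params) {
  nlev <- length(caches)
  dfs <- vector("list", nlev)
  grads <- vector("list", nlev)
  for (l in rev(seq_len(nlev))) {
    r <- pce_cell_bwd(dm, caches[[l]], params$levels[[l]])
    dfs[[l]] <- r$df
    grads[[l]] <- r$grads
    dm <- r$dm
  }
  list(dfs = dfs, level_grads = grads)
}

#' @export
print.pce_config <- function(x, ...) {
  cat("PCE configuration\n")
  cat("  levels:        ", paste(x$level_channels, collapse = " / "), "\n")
  cat("  reduction r:   ", x$reduction_ratio, "\n")
  cat("  memory width:  ", x$memory_dim, "\n")
  cat("  top channels:  ", x$top_channels, "\n")
  invisible(x)
}

#' @export
print.memory_state <- function(x, ...) {
  cat("memory state after level", x$level, "- dim", length(x$m), "\n")
  invisible(x)
}
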