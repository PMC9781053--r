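# Shared builders for compact test models and an element-wise reference
# implementation of the memory cell, kept deliberately independent of
# the package's vectorized code path.

tiny_pcenet <- function(seed = 7, n_classes = 3L, input_size = 32L) {
  pcenet_classifier(stage_channels = c(4L, 8L, 12L, 16L),
                    block_counts = c(1L, 1L, 1L, 1L),
                    input_size = input_size, n_classes = n_classes,
                    reduction_ratio = 4L, seed = seed)
}

small_pcenet <- function(seed = 0, n_classes = 4L) {
  pcenet_classifier(stage_channels = c(32L, 64L, 128L, 256L),
                    block_counts = c(1L, 1L, 1L, 1L),
                    input_size = 64L, n_classes = n_classes,
                    reduction_ratio = 16L, seed = seed)
}

tiny_seqcnn <- function(widths = c(6L, 10L), seed = 1, n_classes = 2L,
                        input_size = 16L) {
  seq_cnn_classifier(widths, seed = seed, n_classes = n_classes,
                     input_size = input_size)
}

random_images <- function(size, n, seed = 99) {
  pcenet:::with_preserved_seed(seed,
    array(stats::runif(size * size * 3 * n), c(size, size, 3L, n)))
}

# Scalar-by-scalar reference for one memory cell step: explicit loops
# and sums, no matrix products.
ref_memory_step <- function(f, m, p) {
  d <- length(m)
  lin1 <- function(x, W, b, j) {
    s <- b[j]
    for (k in seq_along(x)) s <- s + x[k] * W[k, j]
    s
  }
  i <- o <- s <- mn <- numeric(d)
  for (j in seq_len(d)) {
    i[j] <- 1 / (1 + exp(-(lin1(f, p$fi$W, p$fi$b, j) +
                             lin1(m, p$mi$W, p$mi$b, j))))
    o[j] <- 1 / (1 + exp(-(lin1(f, p$fo$W, p$fo$b, j) +
                             lin1(m, p$mo$W, p$mo$b, j))))
  }
  q <- i * m
  for (j in seq_len(d))
    s[j] <- tanh(lin1(f, p$fs$W, p$fs$b, j) + lin1(q, p$ms$W, p$ms$b, j))
  for (j in seq_len(d)) mn[j] <- o[j] * m[j] + (1 - o[j]) * s[j]
  mn
}

# PCE parameter set with every weight and bias zero.
zero_pce_params <- function(cfg) {
  p <- init_pce_params(cfg, seed = 1)
  for (l in seq_along(p$levels))
    for (g in names(p$levels[[l]])) {
      p$levels[[l]][[g]]$W[] <- 0
      p$levels[[l]][[g]]$b[] <- 0
    }
  p$attn$W[] <- 0
  p$attn$b[] <- 0
  p
}
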