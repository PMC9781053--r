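test_that("linear_transform computes x W + b and validates shapes", {
  expect_equal(linear_transform(c(1, 2), diag(2), c(0, 0)), c(1, 2))
  W <- matrix(rnorm(6), 2, 3)
  expect_equal(linear_transform(c(0, 0), W, c(3, -1, 2)), c(3, -1, 2))
  expect_equal(linear_transform(c(1, 2), matrix(c(1, 1, 0, 1), 2, 2),
                                c(1, 1)),
               c(4, 3))
  expect_error(linear_transform(c(1, 2, 3), diag(2), c(0, 0)), "3.*2 x 2")
  expect_error(linear_transform(c(1, 2), diag(2), c(0, 0, 0)), "2 x 2")
})

test_that("global_average_pool returns per-channel spatial means", {
  f <- array(5, c(3, 4, 2))
  expect_equal(global_average_pool(f), c(5, 5))
  f1 <- array(c(7.5, -2), c(1, 1, 2))
  expect_equal(global_average_pool(f1), c(7.5, -2))
  f2 <- array(c(1, 2, 3, 4, rep(0, 4)), c(2, 2, 2))
  expect_equal(global_average_pool(f2), c(2.5, 0))
  expect_error(global_average_pool(matrix(1, 2, 2)), "rank-3")
})

test_that("memory_step matches its zero-parameter closed form", {
  cfg <- pce_config(reduction_ratio = 2, top_channels = 8,
                    level_channels = c(3, 5, 8))
  p <- zero_pce_params(cfg)
  # sigma(0) = 0.5 and tanh(0) = 0, so m' = 0.5 m for any input
  m0 <- memory_state(rep(2, cfg$memory_dim))
  m1 <- memory_step(rep(13.7, 3), m0, p, 1)
  expect_equal(m1$m, rep(1, cfg$memory_dim))
  expect_identical(m1$level, 1L)
  mz <- memory_step(rnorm(3), memory_state(numeric(cfg$memory_dim)), p, 1)
  expect_equal(mz$m, numeric(cfg$memory_dim))
  # three zero-parameter steps scale the initial state by 0.125
  st <- memory_state(c(8, -4, 2, 0))
  for (l in 1:2) st <- memory_step(rnorm(cfg$level_channels[l]), st, p, l)
  expect_equal(st$m, 0.25 * c(8, -4, 2, 0))
})

test_that("vectorized memory cell agrees with the scalar reference", {
  cfg <- pce_config(reduction_ratio = 2, top_channels = 4,
                    level_channels = c(3, 4))
  set.seed(11)
  for (rep_i in 1:100) {
    p <- init_pce_params(cfg)
    f <- rnorm(3)
    m <- rnorm(cfg$memory_dim)
    got <- memory_step(f, m, p, 1)$m
    want <- ref_memory_step(f, m, p$levels[[1]])
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("gates stay in their open ranges and memory stays bounded", {
  cfg <- pce_config(reduction_ratio = 4, top_channels = 16,
                    level_channels = c(6, 10, 16))
  set.seed(21)
  for (rep_i in 1:25) {
    p <- init_pce_params(cfg)
    f <- rnorm(6, sd = 5)
    m <- rnorm(cfg$memory_dim, sd = 5)
    cell <- pcenet:::pce_cell_fwd(matrix(f, 1), matrix(m, 1), p$levels[[1]])
    i <- cell$cache$i; o <- cell$cache$o; s <- cell$cache$s
    expect_true(all(i > 0 & i < 1))
    expect_true(all(o > 0 & o < 1))
    expect_true(all(s > -1 & s < 1))
    # m' is a per-coordinate convex mix of m and a tanh output
    expect_true(all(abs(cell$m) <= pmax(abs(m), 1) + 1e-12))
  }
})

test_that("run_memory_chain composes the per-level steps", {
  cfg <- pce_config(reduction_ratio = 4, top_channels = 8,
                    level_channels = c(3, 5, 8))
  p <- init_pce_params(cfg, seed = 3)
  set.seed(4)
  pyramid <- list(array(rnorm(4 * 4 * 3), c(4, 4, 3)),
                  array(rnorm(2 * 2 * 5), c(2, 2, 5)),
                  array(rnorm(1 * 1 * 8), c(1, 1, 8)))
  got <- run_memory_chain(pyramid, p)
  manual <- memory_state(numeric(cfg$memory_dim))
  for (l in 1:2)
    manual <- memory_step(global_average_pool(pyramid[[l]]), manual, p, l)
  expect_equal(got$m, manual$m)
  expect_identical(got$level, 2L)
  expect_equal(run_memory_chain(pyramid, p)$m, got$m) # purely functional
  # with zero parameters the chain ignores its input entirely
  pz <- zero_pce_params(cfg)
  other <- lapply(pyramid, function(f) f + 100)
  expect_equal(run_memory_chain(pyramid, pz)$m, run_memory_chain(other, pz)$m)
})

test_that("contextual_attention projects the cue to top channels", {
  cfg <- pce_config(reduction_ratio = 4, top_channels = 8,
                    level_channels = c(3, 8))
  p <- init_pce_params(cfg, seed = 5)
  p$attn$W[] <- 0
  p$attn$b[] <- 1
  expect_equal(contextual_attention(rnorm(cfg$memory_dim), p), rep(1, 8))
  p2 <- init_pce_params(cfg, seed = 6)
  expect_equal(contextual_attention(numeric(cfg$memory_dim), p2), p2$attn$b)
  m <- rnorm(cfg$memory_dim)
  expect_equal(contextual_attention(m, p2),
               as.numeric(matrix(m, 1) %*% p2$attn$W) + p2$attn$b)
})

test_that("apply_attention scales channels and preserves shape", {
  f4 <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  expect_equal(apply_attention(f4, c(1, 1)), f4)
  expect_equal(apply_attention(f4, c(0, 0)), f4 * 0)
  got <- apply_attention(f4, c(2, 0.5))
  expect_equal(got[, , 1], f4[, , 1] * 2)
  expect_equal(got[, , 2], f4[, , 2] * 0.5)
  expect_identical(dim(got), dim(f4))
  set.seed(8)
  for (rep_i in 1:10) {
    h <- sample(1:5, 1); w <- sample(1:5, 1); c <- sample(1:6, 1)
    fi <- array(rnorm(h * w * c), c(h, w, c))
    expect_identical(dim(apply_attention(fi, rnorm(c))), dim(fi))
  }
  expect_error(apply_attention(f4, c(1, 2, 3)), "channels")
})

test_that("pce_config enforces its dimensional invariants", {
  cfg <- pce_config()
  expect_equal(cfg$memory_dim, 128L)
  expect_equal(cfg$level_channels, c(256L, 512L, 1024L, 2048L))
  expect_error(pce_config(reduction_ratio = 15), "divisible")
  expect_error(pce_config(level_channels = c(256, 512)), "top_channels")
})
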