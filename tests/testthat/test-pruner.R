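test_that("filter L1 norms sum absolute kernel weights per filter", {
  w <- array(0, c(3, 3, 2, 4))
  expect_equal(filter_l1_norms(w)$norms, rep(0, 4))
  w1 <- array(-3, c(1, 1, 1, 1))
  expect_equal(filter_l1_norms(w1)$norms, 3)
  w2 <- array(c(1, -2, 0.5, 0), c(2, 2, 1, 1))
  expect_equal(filter_l1_norms(w2)$norms, 3.5)
  # bias never enters: the table is built from the 4-way weight only
  expect_error(filter_l1_norms(matrix(1, 2, 2)), "4-way")
  expect_error(filter_l1_norms(rnorm(5)), "4-way")
})

test_that("filter selection takes the m smallest norms, stably", {
  expect_equal(select_filters_to_prune(c(3, 1, 2), 1), 2L)
  expect_equal(select_filters_to_prune(c(3, 1, 2), 0), integer(0))
  # ties keep the lower index
  expect_equal(select_filters_to_prune(c(5, 2, 2, 2), 2), c(2L, 3L))
  expect_error(select_filters_to_prune(c(1, 2), 2), "cannot prune all")
  expect_error(select_filters_to_prune(c(1, 2), -1), "0 <= m")
  set.seed(33)
  for (rep_i in 1:200) {
    v <- round(rnorm(sample(5:50, 1)), 2)
    m <- sample(0:(length(v) - 1L), 1)
    got <- select_filters_to_prune(v, m)
    # brute force: full sort, take the bottom m
    want <- sort(order(v)[seq_len(m)])
    expect_identical(got, as.integer(want))
    expect_length(union(got, setdiff(seq_along(v), got)), length(v))
  }
})

test_that("coupled groups partition the prunable layers", {
  m <- tiny_pcenet()
  gr <- coupled_layer_groups(m)
  # one shared group per stage output plus the stem and the inner convs
  expect_setequal(grep("\\.out$", names(gr), value = TRUE),
                  c("s1.out", "s2.out", "s3.out", "s4.out"))
  expect_true(all(c("s1.b1.conv3.W", "s1.b1.down.W") %in%
                    gr$s1.out$producers))
  expect_true("pce.l1.fi.W" %in% gr$s1.out$consumers)
  expect_true("pce.attn.W" %in% gr$s4.out$consumers)
  expect_true("head.W" %in% gr$s4.out$consumers)
  # every producer appears in exactly one group
  prod <- unlist(lapply(gr, `[[`, "producers"))
  expect_false(anyDuplicated(prod) > 0)
  # single-path CNN: every conv is its own group
  sq <- tiny_seqcnn(c(5L, 7L, 9L))
  gsq <- coupled_layer_groups(sq)
  expect_length(gsq, 3L)
  expect_true(all(vapply(gsq, function(g) length(g$producers) == 1L, TRUE)))
  # a single residual block groups its expansion conv with the shortcut
  m1 <- build_model(backbone_config(16L, 1L, input_size = 32L,
                                    n_classes = 2L), seed = 1)
  g1 <- coupled_layer_groups(m1)
  expect_setequal(g1$s1.out$producers, c("s1.b1.conv3.W", "s1.b1.down.W"))
})

test_that("pruning plans hit the requested widths", {
  m <- small_pcenet()
  p25 <- build_pruning_plan(m, 0.25)
  keeps <- vapply(paste0("s", 1:4, ".out"),
                  function(g) length(p25$groups[[g]]$keep), 1L)
  expect_equal(unname(keeps), c(24L, 48L, 96L, 192L))
  p50 <- build_pruning_plan(m, 0.5)
  keeps <- vapply(paste0("s", 1:4, ".out"),
                  function(g) length(p50$groups[[g]]$keep), 1L)
  expect_equal(unname(keeps), c(16L, 32L, 64L, 128L))
  p0 <- build_pruning_plan(m, 0)
  expect_true(all(vapply(p0$groups, function(g) g$m == 0L, TRUE)))
  expect_true(all(vapply(p0$groups,
                         function(g) identical(g$keep, seq_len(g$n)), TRUE)))
  expect_error(build_pruning_plan(m, 1), "\\[0, 1\\)")
  expect_error(build_pruning_plan(m, -0.1), "\\[0, 1\\)")
  # count conservation per layer
  for (g in p25$groups) expect_equal(length(g$keep) + g$m, g$n)
})

test_that("identity plans leave the network function unchanged", {
  m <- tiny_pcenet(seed = 5)
  plan <- build_pruning_plan(m, 0)
  pruned <- apply_plan(m, plan)
  x <- random_images(32, 10)
  expect_equal(forward_features(pruned, x)$logits,
               forward_features(m, x)$logits, tolerance = 1e-6)
})

test_that("pruning zeroed filters preserves the function", {
  # single-path network: zero one filter end to end, then prune just it
  sq <- tiny_seqcnn(c(6L, 8L), seed = 12, input_size = 16L)
  j <- 4L
  sq$params$c1.W[, , , j] <- 0
  sq$params$bn1.gamma[j] <- 0
  sq$params$bn1.beta[j] <- 0
  plan <- build_pruning_plan(sq, 0)
  plan$groups$c1$keep <- setdiff(seq_len(6L), j)
  plan$groups$c1$m <- 1L
  pruned <- apply_plan(sq, plan)
  x <- random_images(16, 8)
  expect_equal(forward_features(pruned, x)$logits,
               forward_features(sq, x)$logits, tolerance = 1e-5)
  # residual stage: zero channel k in every producer of the shared group
  m <- tiny_pcenet(seed = 6)
  k <- 2L
  m$params$s2.b1.conv3.W[, , , k] <- 0
  m$params$s2.b1.bn3.gamma[k] <- 0
  m$params$s2.b1.bn3.beta[k] <- 0
  m$params$s2.b1.down.W[, , , k] <- 0
  m$params$s2.b1.dbn.gamma[k] <- 0
  m$params$s2.b1.dbn.beta[k] <- 0
  plan <- build_pruning_plan(m, 0)
  plan$groups$s2.out$keep <- setdiff(seq_len(8L), k)
  plan$groups$s2.out$m <- 1L
  pruned <- apply_plan(m, plan)
  x <- random_images(32, 6)
  expect_equal(forward_features(pruned, x)$logits,
               forward_features(m, x)$logits, tolerance = 1e-5)
})

test_that("parameter count decreases monotonically in the ratio", {
  m <- small_pcenet(seed = 2)
  counts <- vapply(c(0, 0.1, 0.25, 0.5, 0.75), function(r) {
    count_parameters(apply_plan(m, build_pruning_plan(m, r)))$total_params
  }, 1)
  expect_true(all(diff(counts) < 0))
  expect_equal(counts[1], count_parameters(m)$total_params)
  # both in- and out-widths shrink, so conv parameters scale
  # super-linearly: at ratio 0.5 the model is well under half size
  expect_lt(counts[4], 0.5 * counts[1])
})

test_that("plan application validates against the model", {
  m <- tiny_pcenet()
  other <- small_pcenet()
  expect_error(apply_plan(m, build_pruning_plan(other, 0.25)),
               "layer group")
  plan <- build_pruning_plan(m, 0)
  plan$groups$s1.out <- NULL
  expect_error(apply_plan(m, plan), "s1.out")
})

test_that("plans and pruned checkpoints survive a round trip", {
  m <- tiny_pcenet(seed = 8)
  plan <- build_pruning_plan(m, 0.25)
  pf <- tempfile(fileext = ".json")
  write_pruning_plan(plan, pf)
  plan2 <- read_pruning_plan(pf)
  expect_equal(plan2$ratio, plan$ratio)
  expect_identical(lapply(plan2$groups, `[[`, "keep"),
                   lapply(plan$groups, `[[`, "keep"))
  pruned <- apply_plan(m, plan2)
  ck <- tempfile(fileext = ".ckpt")
  save_checkpoint(pruned, ck)
  back <- load_checkpoint(ck)
  x <- random_images(32, 4)
  expect_equal(forward_features(back, x)$logits,
               forward_features(pruned, x)$logits)
  unlink(c(pf, ck))
})

test_that("surviving weights are copied, not reinitialized", {
  m <- tiny_pcenet(seed = 10)
  plan <- build_pruning_plan(m, 0.25)
  pruned <- apply_plan(m, plan)
  keep_in <- plan$groups$conv1$keep
  expect_identical(pruned$params$conv1.W,
                   m$params$conv1.W[, , , keep_in, drop = FALSE])
  k1 <- plan$groups$`s1.b1.w1`$keep
  expect_identical(pruned$params$s1.b1.conv1.W,
                   m$params$s1.b1.conv1.W[, , keep_in, k1, drop = FALSE])
  ks4 <- plan$groups$s4.out$keep
  expect_identical(pruned$params$head.W, m$params$head.W[ks4, ])
  expect_identical(pruned$params$pce.attn.W, m$params$pce.attn.W[, ks4])
  expect_identical(pruned$buffers$s1.b1.bn1.mean,
                   m$buffers$s1.b1.bn1.mean[k1])
})
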