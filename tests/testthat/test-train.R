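test_that("confusion matrices count true rows against predicted columns", {
  cr <- pcenet:::confusion_report
  perfect <- cr(c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0), c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0),
                c("a", "b", "c"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$confusion, diag(c(4L, 3L, 3L)), ignore_attr = TRUE)
  expect_equal(perfect$n_eval, 10L)
  constant <- cr(rep(0:3, each = 5), rep(2L, 20), letters[1:4])
  expect_equal(constant$accuracy, 0.25)
  expect_true(all(constant$confusion[, -3] == 0))
  hand <- cr(c(0, 1, 1), c(0, 0, 1), c("x", "y"))
  expect_equal(hand$accuracy, 2 / 3)
  expect_equal(hand$confusion,
               matrix(c(1L, 1L, 0L, 1L), 2, 2), ignore_attr = TRUE)
  expect_equal(sum(hand$confusion), hand$n_eval)
  expect_equal(hand$per_class_recall, c(x = 1, y = 0.5), ignore_attr = TRUE)
})

test_that("accuracy is invariant under consistent class relabeling", {
  cr <- pcenet:::confusion_report
  set.seed(14)
  truth <- sample(0:3, 40, replace = TRUE)
  pred <- sample(0:3, 40, replace = TRUE)
  base <- cr(truth, pred, letters[1:4])
  perm <- sample(0:3)
  relab <- cr(perm[truth + 1], perm[pred + 1], letters[1:4])
  expect_equal(relab$accuracy, base$accuracy)
  expect_equal(sum(relab$confusion), sum(base$confusion))
})

test_that("split_dataset partitions reproducibly", {
  set <- generate_fixture(fixture_spec(n_classes = 2, images_per_class = 5,
                                       image_size = 16, seed = 1))
  sp <- split_dataset(set, 0.8, seed = 3)
  expect_equal(dim(sp$train$images)[4], 8L)
  expect_equal(dim(sp$eval$images)[4], 2L)
  expect_identical(sp$train$split, "train")
  # partition law: disjoint and exhaustive on the image level
  key <- function(s) apply(s$images, 4, function(im) paste(head(im, 8),
                                                           collapse = ","))
  expect_length(intersect(key(sp$train), key(sp$eval)), 0L)
  expect_setequal(c(key(sp$train), key(sp$eval)), key(set))
  sp2 <- split_dataset(set, 0.8, seed = 3)
  expect_identical(sp2$train$images, sp$train$images)
  sp3 <- split_dataset(set, 0.8, seed = 4)
  expect_false(identical(sp3$train$labels, sp$train$labels) &&
                 identical(sp3$train$images, sp$train$images))
  one <- subset_image_set(set, 1)
  expect_error(split_dataset(one, 0.8), "at least 2")
  expect_error(split_dataset(set, 1.2), "\\(0, 1\\)")
})

test_that("zero learning rate leaves parameters untouched", {
  m <- tiny_seqcnn(c(4L, 6L), seed = 2, input_size = 16L)
  set <- generate_fixture(fixture_spec(n_classes = 2, images_per_class = 4,
                                       image_size = 16, seed = 2))
  tc <- train_config(batch_size = 4, initial_lr = 0, epochs = 1, seed = 1,
                     input_size = 16)
  run <- train_model(m, set, tc)
  expect_identical(run$model$params, m$params)
  expect_equal(nrow(run$history), 1L)
})

test_that("training is deterministic given the seed", {
  m <- tiny_seqcnn(c(4L, 6L), seed = 3, input_size = 16L)
  set <- generate_fixture(fixture_spec(n_classes = 2, images_per_class = 6,
                                       image_size = 16, seed = 5))
  tc <- train_config(batch_size = 4, initial_lr = 0.01, epochs = 2,
                     seed = 11, input_size = 16)
  r1 <- train_model(m, set, tc)
  r2 <- train_model(m, set, tc)
  expect_identical(r1$history$loss, r2$history$loss)
  expect_identical(r1$model$params, r2$model$params)
})

test_that("a separable two-class set is learned quickly", {
  set <- generate_fixture(fixture_spec(n_classes = 2, images_per_class = 32,
                                       image_size = 32, seed = 0))
  m <- tiny_seqcnn(c(8L, 16L), seed = 0, n_classes = 2L, input_size = 32L)
  tc <- train_config(batch_size = 16, initial_lr = 0.01, epochs = 5,
                     seed = 0, input_size = 32)
  run <- train_model(m, set, tc)
  expect_gt(run$history$train_acc[5], 0.9)
  # loss history is recorded per epoch
  expect_equal(run$history$epoch, 1:5)
})

test_that("fine-tuning warm-starts from surviving weights", {
  m <- tiny_seqcnn(c(8L, 12L), seed = 4, input_size = 16L)
  set <- generate_fixture(fixture_spec(n_classes = 2, images_per_class = 16,
                                       image_size = 16, seed = 7))
  tc <- train_config(batch_size = 8, initial_lr = 0.01, epochs = 3,
                     seed = 2, input_size = 16)
  base <- train_model(m, set, tc)
  plan <- build_pruning_plan(base$model, 0.25)
  pruned <- apply_plan(base$model, plan)
  # zero epochs: the model comes back unchanged
  tc0 <- train_config(batch_size = 8, initial_lr = 0.01, epochs = 0,
                      seed = 2, input_size = 16)
  expect_identical(finetune_model(pruned, set, tc0)$model$params,
                   pruned$params)
  # warm start beats a cold start of the same architecture at epoch 1
  tc1 <- train_config(batch_size = 8, initial_lr = 0.01, epochs = 1,
                      seed = 2, input_size = 16)
  warm <- finetune_model(pruned, set, tc1)
  cold_model <- seq_cnn_classifier(vapply(pruned$arch$convs,
                                          function(cv) cv$cout, 1L),
                                   seed = 90, n_classes = 2L,
                                   input_size = 16L)
  cold <- train_model(cold_model, set, tc1)
  expect_lt(warm$history$loss[1], cold$history$loss[1])
})

test_that("training rejects malformed inputs", {
  m <- tiny_seqcnn(c(4L), seed = 1, input_size = 16L)
  set <- generate_fixture(fixture_spec(n_classes = 2, images_per_class = 2,
                                       image_size = 16, seed = 1))
  bad <- set
  bad$labels[1] <- 5L
  tc <- train_config(batch_size = 2, epochs = 1, input_size = 16)
  expect_error(train_model(m, bad, tc))
  tc2 <- train_config(batch_size = 2, epochs = 1, input_size = 32)
  expect_error(train_model(m, set, tc2), "input_size")
})
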