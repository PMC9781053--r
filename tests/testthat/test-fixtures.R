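test_that("fixture generation is a pure function of its spec", {
  spec <- fixture_spec(n_classes = 3, images_per_class = 2, image_size = 24,
                       seed = 7)
  a <- generate_fixture(spec)
  b <- generate_fixture(spec)
  expect_identical(a$images, b$images)
  expect_identical(a$labels, b$labels)
  d <- generate_fixture(fixture_spec(n_classes = 3, images_per_class = 2,
                                     image_size = 24, seed = 8))
  expect_false(identical(d$images, a$images))
})

test_that("fixtures are balanced with in-range labels", {
  set <- generate_fixture(fixture_spec(n_classes = 7, images_per_class = 10,
                                       image_size = 16, seed = 0))
  expect_equal(dim(set$images)[4], 70L)
  expect_setequal(unique(set$labels), 0:6)
  expect_true(all(table(set$labels) == 10))
  expect_length(set$class_names, 7L)
  expect_true(all(set$images >= 0 & set$images <= 1))
})

test_that("image folders round-trip labels, names and counts", {
  set <- generate_fixture(fixture_spec(n_classes = 3, images_per_class = 4,
                                       image_size = 16, seed = 2,
                                       class_names = c("b_mid", "a_low",
                                                       "c_high")))
  dir <- tempfile("imgset")
  write_image_folder(set, dir)
  expect_setequal(list.dirs(dir, recursive = FALSE, full.names = FALSE),
                  c("b_mid", "a_low", "c_high"))
  back <- read_image_folder(dir)
  expect_equal(dim(back$images)[4], 12L)
  # reader assigns labels by sorted directory name
  expect_identical(back$class_names, c("a_low", "b_mid", "c_high"))
  expect_true(all(table(back$labels) == 4))
  # pixel data survives the 8-bit PNG round trip
  first_a <- which(set$labels == which(set$class_names == "a_low") - 1L)[1]
  expect_equal(back$images[, , , which(back$labels == 0L)[1]],
               set$images[, , , first_a], tolerance = 1 / 255)
  unlink(dir, recursive = TRUE)
})

test_that("grayscale images are promoted to RGB on read", {
  dir <- tempfile("gray")
  dir.create(file.path(dir, "only"), recursive = TRUE)
  g <- matrix(seq(0, 1, length.out = 64), 8, 8)
  png::writePNG(g, file.path(dir, "only", "g.png"))
  png::writePNG(array(runif(192), c(8, 8, 3)),
                file.path(dir, "only", "rgb.png"))
  set <- read_image_folder(dir)
  expect_equal(dim(set$images)[1:3], c(8L, 8L, 3L))
  expect_equal(set$images[, , 1, 1], set$images[, , 3, 1])
  unlink(dir, recursive = TRUE)
})

test_that("degenerate folders and sets are refused", {
  empty <- tempfile("empty")
  dir.create(empty)
  expect_error(read_image_folder(empty), "no class subdirectories")
  expect_error(read_image_folder(tempfile("missing")), "no such directory")
  set <- generate_fixture(fixture_spec(n_classes = 2, images_per_class = 1,
                                       image_size = 16, seed = 1))
  none <- set
  none$images <- set$images[, , , 0, drop = FALSE]
  none$labels <- integer(0)
  expect_error(write_image_folder(none, tempfile()), "empty dataset")
})

test_that("the default fixture is separable by a small CNN", {
  set <- generate_fixture(fixture_spec(n_classes = 7, images_per_class = 30,
                                       image_size = 32, seed = 0))
  sp <- split_dataset(set, 0.8, seed = 0)
  m <- seq_cnn_classifier(c(8L, 16L, 32L), seed = 0, n_classes = 7L,
                          input_size = 32L)
  tc <- train_config(batch_size = 16, initial_lr = 0.01, epochs = 5,
                     seed = 0, input_size = 32)
  run <- train_model(m, sp$train, tc)
  acc <- evaluate_model(run$model, sp$eval)$accuracy
  expect_gt(acc, 0.5)  # chance is 1/7
})

test_that("bilinear resize preserves constants and hits the target size", {
  x <- array(0.4, c(20, 20, 3, 2))
  y <- pcenet:::resize_images(x, 16)
  expect_equal(dim(y), c(16L, 16L, 3L, 2L))
  expect_equal(as.numeric(y), rep(0.4, length(y)))
  # identity when sizes already match
  expect_identical(pcenet:::resize_images(x, 20), x)
})
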