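#' Labeled image set
#'
#' The in-memory dataset container: an (H, W, 3, N) array of RGB images
#' in [0, 1], 0-based integer labels, class names, and an optional split
#' tag.
#'
#' @param images (H, W, 3, N) numeric array (a single (H, W, 3) image is
#'   promoted).
#' @param labels Integer labels in `0..(n_classes - 1)`, one per image.
#' @param class_names Unique class names; label `k` means
#'   `class_names[k + 1]`.
#' @param split Optional tag such as "train" or "eval".
#' @return Object of class `labeled_image_set`.
#' @export
labeled_image_set <- function(images, labels, class_names, split = NULL) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  stopifnot(length(dim(images)) == 4L, dim(images)[3] == 3L)
  labels <- as.integer(labels)
  if (length(labels) != dim(images)[4])
    stop("labeled_image_set: ", dim(images)[4], " images but ",
         length(labels), " labels")
  if (anyDuplicated(class_names))
    stop("labeled_image_set: class names must be unique")
  if (any(labels < 0L) || any(labels >= length(class_names)))
    stop("labeled_image_set: labels must lie in 0..",
         length(class_names) - 1L)
  structure(list(images = images, labels = labels,
                 class_names = as.character(class_names), split = split),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("Labeled image set: %d images (%dx%d), %d classes%s\n",
              d[4], d[1], d[2], length(x$class_names),
              if (is.null(x$split)) "" else paste0(" [", x$split, "]")))
  tb <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                     labels = x$class_names))
  cat(" ", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Take a subset of a labeled image set
#'
#' @param set A [labeled_image_set()].
#' @param idx 1-based image indices.
#' @param split Optional new split tag.
#' @return The subset as a `labeled_image_set`.
#' @export
subset_image_set <- function(set, idx, split = set$split) {
  labeled_image_set(set$images[, , , idx, drop = FALSE], set$labels[idx],
                    set$class_names, split)
}

#' Synthetic fixture specification
#'
#' Describes a seeded synthetic classification task emulating crop/seed
#' image data: each class has a base color, a texture primitive and a
#' noise level, and every image shows one elliptical object (bean- or
#' leaf-like) on a lighter background. Textures caricature the visual
#' cues that separate real classes (cracks for broken/fractioned
#' produce, dark spots for mold, gray mottling for unfermented
#' surfaces); they make classes separable by a small CNN without any
#' claim of visual realism.
#'
#' @param n_classes Number of classes (default 7, the bean-like task;
#'   use 4 for the leaf-like task).
#' @param images_per_class Images generated per class.
#' @param image_size Square image size in pixels.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param class_names Optional names (defaults to class1..classK).
#' @return Object of class `fixture_spec` with per-class `signatures`.
#' @export
fixture_spec <- function(n_classes = 7L, images_per_class = 10L,
                         image_size = 64L, seed = 0L, noise_sd = 0.05,
                         class_names = NULL) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("fixture_spec: need at least 2 classes")
  if (images_per_class < 1L)
    stop("fixture_spec: images_per_class must be >= 1")
  if (image_size < 16L) stop("fixture_spec: image_size must be >= 16")
  if (is.null(class_names))
    class_names <- sprintf("class%d", seq_len(n_classes))
  if (length(class_names) != n_classes)
    stop("fixture_spec: need one class name per class")
  textures <- c("plain", "cracked", "spotted", "mottled")
  hues <- (seq_len(n_classes) - 1L) / n_classes
  signatures <- lapply(seq_len(n_classes), function(k) {
    # alternate brightness so neighbouring hues stay far apart in RGB
    base <- grDevices::col2rgb(
      grDevices::hsv(hues[k], 0.8, if (k %% 2L) 0.75 else 0.4))[, 1] / 255
    list(base_rgb = as.numeric(base),
         texture = textures[(k - 1L) %% length(textures) + 1L],
         noise_sd = noise_sd)
  })
  structure(list(n_classes = n_classes,
                 images_per_class = as.integer(images_per_class),
                 image_size = as.integer(image_size),
                 seed = as.integer(seed),
                 class_names = as.character(class_names),
                 signatures = signatures),
            class = "fixture_spec")
}

draw_fixture_image <- function(size, sig) {
  gx <- matrix(rep(seq_len(size), each = size), size, size)
  gy <- matrix(rep(seq_len(size), times = size), size, size)
  bg <- 0.82 + stats::rnorm(3, 0, 0.03)
  img <- array(rep(bg, each = size * size), c(size, size, 3L))
  # elliptical object
  cx <- size * stats::runif(1, 0.4, 0.6)
  cy <- size * stats::runif(1, 0.4, 0.6)
  a <- size * stats::runif(1, 0.3, 0.42)
  b <- size * stats::runif(1, 0.22, 0.32)
  th <- stats::runif(1, 0, pi)
  xr <- (gx - cx) * cos(th) + (gy - cy) * sin(th)
  yr <- -(gx - cx) * sin(th) + (gy - cy) * cos(th)
  inside <- (xr / a)^2 + (yr / b)^2 <= 1
  shade <- 1 - 0.25 * ((xr / a)^2 + (yr / b)^2)  # gentle 3D shading
  col <- sig$base_rgb * (1 + stats::rnorm(3, 0, 0.04))
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[inside] <- (col[ch] * shade)[inside]
    img[, , ch] <- pl
  }
  if (sig$texture == "cracked") {
    for (i in seq_len(2L + stats::rpois(1, 1))) {
      p0 <- c(cx, cy) + stats::runif(2, -a / 2, a / 2)
      ang <- stats::runif(1, 0, pi)
      dxy <- c(cos(ang), sin(ang))
      dist <- abs((gx - p0[1]) * dxy[2] - (gy - p0[2]) * dxy[1])
      crack <- inside & dist < max(size / 64, 1)
      for (ch in 1:3) {
        pl <- img[, , ch]; pl[crack] <- pl[crack] * 0.25; img[, , ch] <- pl
      }
    }
  } else if (sig$texture == "spotted") {
    for (i in seq_len(5L + stats::rpois(1, 3))) {
      sc <- c(cx, cy) + stats::runif(2, -0.6, 0.6) * c(a, b)
      rad <- size * stats::runif(1, 0.02, 0.05)
      spot <- inside & ((gx - sc[1])^2 + (gy - sc[2])^2 <= rad^2)
      for (ch in 1:3) {
        pl <- img[, , ch]; pl[spot] <- pl[spot] * 0.3; img[, , ch] <- pl
      }
    }
  } else if (sig$texture == "mottled") {
    coarse <- matrix(stats::rnorm(64), 8, 8)
    up <- coarse[pmin(8L, ceiling(gx / size * 8)) +
                   8L * (pmin(8L, ceiling(gy / size * 8)) - 1L)]
    mott <- inside & (matrix(up, size, size) > 0.3)
    gray <- mean(sig$base_rgb) * 1.35
    for (ch in 1:3) {
      pl <- img[, , ch]; pl[mott] <- 0.6 * pl[mott] + 0.4 * gray
      img[, , ch] <- pl
    }
  }
  img <- img + array(stats::rnorm(length(img), 0, sig$noise_sd), dim(img))
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic labeled image set
#'
#' A pure function of the spec: the same spec (including seed) yields a
#' byte-identical dataset. Classes are balanced at exactly
#' `images_per_class` each.
#'
#' @param spec A [fixture_spec()].
#' @return A [labeled_image_set()].
#' @export
#' @examples
#' set <- generate_fixture(fixture_spec(n_classes = 3, images_per_class = 2,
#'                                      image_size = 32))
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_preserved_seed(spec$seed, {
    sz <- spec$image_size
    n <- spec$n_classes * spec$images_per_class
    images <- array(0, c(sz, sz, 3L, n))
    labels <- integer(n)
    ix <- 1L
    for (k in seq_len(spec$n_classes)) {
      for (i in seq_len(spec$images_per_class)) {
        images[, , , ix] <- draw_fixture_image(sz, spec$signatures[[k]])
        labels[ix] <- k - 1L
        ix <- ix + 1L
      }
    }
    labeled_image_set(images, labels, spec$class_names)
  })
}

#' Write a labeled image set as an image folder
#'
#' Standard class-subdirectory layout: one subdirectory per class, PNG
#' files inside.
#'
#' @param set A [labeled_image_set()].
#' @param path Target directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_image_folder <- function(set, path) {
  stopifnot(inherits(set, "labeled_image_set"))
  if (dim(set$images)[4] == 0L)
    stop("write_image_folder: refusing to write an empty dataset")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  counter <- integer(length(set$class_names))
  for (i in seq_len(dim(set$images)[4])) {
    k <- set$labels[i] + 1L
    d <- file.path(path, set$class_names[k])
    if (!dir.exists(d)) dir.create(d)
    counter[k] <- counter[k] + 1L
    png::writePNG(set$images[, , , i],
                  file.path(d, sprintf("img_%05d.png", counter[k])))
  }
  invisible(path)
}

#' Read an image-folder dataset
#'
#' Class names are the sorted subdirectory names; labels are assigned in
#' that order (0-based). Grayscale images are promoted to 3-channel RGB
#' by channel replication; alpha channels are dropped. All images must
#' share one size (resize at training time handles mixed sources).
#'
#' @param path Directory with one subdirectory per class.
#' @return A [labeled_image_set()].
#' @export
read_image_folder <- function(path) {
  if (!dir.exists(path)) stop("read_image_folder: no such directory: ", path)
  classes <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L)
    stop("read_image_folder: ", path, " contains no class subdirectories")
  files <- list(); labels <- integer(0)
  for (k in seq_along(classes)) {
    fs <- sort(list.files(file.path(path, classes[k]),
                          pattern = "\\.(png|PNG)$", full.names = TRUE))
    if (length(fs) == 0L)
      stop("read_image_folder: class directory '", classes[k],
           "' has no PNG images")
    files <- c(files, fs)
    labels <- c(labels, rep(k - 1L, length(fs)))
  }
  imgs <- lapply(files, function(f) {
    img <- tryCatch(png::readPNG(f),
                    error = function(e)
                      stop("read_image_folder: cannot decode ", f, ": ",
                           conditionMessage(e)))
    to_rgb(img)
  })
  d1 <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(i) identical(dim(i), d1), TRUE)))
    stop("read_image_folder: images have mixed sizes; resize them first")
  images <- array(unlist(imgs), c(d1, length(imgs)))
  labeled_image_set(images, labels, classes)
}

to_rgb <- function(img) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  ch <- dim(img)[3]
  if (ch == 1L) array(rep(img, 3L), c(dim(img)[1:2], 3L))
  else if (ch == 2L) array(rep(img[, , 1L], 3L), c(dim(img)[1:2], 3L))
  else if (ch >= 3L) img[, , 1:3, drop = FALSE]
  else stop("unsupported channel count: ", ch)
}

# Bilinear resize of an (H, W, 3, N) stack to size x size.
resize_images <- function(images, size) {
  d <- dim(images)
  if (length(d) == 3L) { dim(images) <- c(d, 1L); d <- dim(images) }
  if (d[1] == size && d[2] == size) return(images)
  src_h <- d[1]; src_w <- d[2]
  # align-corners-free mapping
  ys <- pmin(pmax((seq_len(size) - 0.5) * src_h / size + 0.5 - 0.5, 1),
             src_h)
  xs <- pmin(pmax((seq_len(size) - 0.5) * src_w / size + 0.5 - 0.5, 1),
             src_w)
  y0 <- floor(ys); y1 <- pmin(y0 + 1, src_h); wy <- ys - y0
  x0 <- floor(xs); x1 <- pmin(x0 + 1, src_w); wx <- xs - x0
  out <- array(0, c(size, size, d[3], d[4]))
  m <- matrix(images, nrow = src_h)  # columns indexed (w, c, n)
  colix <- function(xcol) {
    # column indices in m for source column vector xcol (length size)
    outer(xcol, (seq_len(d[3] * d[4]) - 1L) * src_w, `+`)
  }
  c00 <- m[cbind(rep(y0, times = size * d[3] * d[4]),
                 as.vector(colix(rep(x0, each = size))))]
  c01 <- m[cbind(rep(y0, times = size * d[3] * d[4]),
                 as.vector(colix(rep(x1, each = size))))]
  c10 <- m[cbind(rep(y1, times = size * d[3] * d[4]),
                 as.vector(colix(rep(x0, each = size))))]
  c11 <- m[cbind(rep(y1, times = size * d[3] * d[4]),
                 as.vector(colix(rep(x1, each = size))))]
  wyv <- rep(wy, times = size * d[3] * d[4])
  wxv <- rep(rep(wx, each = size), times = d[3] * d[4])
  v <- (1 - wyv) * (1 - wxv) * c00 + (1 - wyv) * wxv * c01 +
    wyv * (1 - wxv) * c10 + wyv * wxv * c11
  array(v, c(size, size, d[3], d[4]))
}
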