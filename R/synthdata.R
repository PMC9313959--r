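# Seeded synthetic two-class chest-image generator and image-folder I/O.
# Class 0 ("normal") is a smooth low-frequency background; class 1
# ("pneumonia") is the same background plus mid-frequency Gaussian-blob
# opacities whose amplitude scales with `texture_gap`. This is a tunable,
# learnable texture family emulating the visual contrast between clear and
# opacified lung fields -- not a radiological simulation.

#' Synthetic dataset configuration
#'
#' @param n_train,n_test number of training / test images.
#' @param image_size `c(H, W)` in pixels.
#' @param class_ratio fraction of class-1 (pneumonia) images; the default
#'   emulates the 4273:1583 imbalance of the public pediatric chest X-ray
#'   collection this generator stands in for.
#' @param texture_gap real in `[0, 1]`: amplitude of the class-1 blob
#'   texture. `0` makes the two classes distributionally identical; `1` is
#'   a strongly separable task.
#' @param seed integer seed; identical configurations yield byte-identical
#'   datasets. Train and test draw from disjoint seed streams.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_train = 200L, n_test = 100L,
                         image_size = c(64L, 64L),
                         class_ratio = 4273 / 5856, texture_gap = 1,
                         seed = 1L) {
  if (n_train < 1L || n_test < 1L)
    stop("n_train and n_test must be >= 1", call. = FALSE)
  if (length(image_size) != 2L || any(image_size < 8L))
    stop("image_size must be c(H, W) with H, W >= 8", call. = FALSE)
  if (class_ratio <= 0 || class_ratio >= 1)
    stop("class_ratio must lie in (0, 1)", call. = FALSE)
  if (texture_gap < 0 || texture_gap > 1)
    stop("texture_gap must lie in [0, 1]", call. = FALSE)
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 image_size = as.integer(image_size),
                 class_ratio = class_ratio, texture_gap = texture_gap,
                 seed = as.integer(seed)),
            class = "synth_config")
}

gauss_blob <- function(H, W, cy, cx, sy, sx) {
  outer(exp(-(seq_len(H) - cy)^2 / (2 * sy^2)),
        exp(-(seq_len(W) - cx)^2 / (2 * sx^2)))
}

synth_image <- function(H, W, label, gap) {
  # shared low-frequency anatomy-like background
  img <- matrix(0.35, H, W)
  img <- img + 0.08 * outer(seq(-1, 1, length.out = H), rep(1, W))
  for (i in 1:2) {
    img <- img + stats::runif(1, 0.1, 0.25) *
      gauss_blob(H, W, stats::runif(1, 0.25 * H, 0.75 * H),
                 stats::runif(1, 0.25 * W, 0.75 * W),
                 stats::runif(1, 0.35 * H, 0.6 * H),
                 stats::runif(1, 0.35 * W, 0.6 * W))
  }
  img <- img + matrix(stats::rnorm(H * W, 0, 0.04), H, W)
  if (label == 1L) {
    # mid-frequency opacities; amplitude carries the class signal
    for (i in 1:6) {
      img <- img + gap * stats::runif(1, 0.25, 0.45) *
        gauss_blob(H, W, stats::runif(1, 0.15 * H, 0.85 * H),
                   stats::runif(1, 0.15 * W, 0.85 * W),
                   stats::runif(1, H / 16, H / 8),
                   stats::runif(1, W / 16, W / 8))
    }
  }
  pmin(pmax(img, 0), 1)
}

synth_split <- function(n, cfg, seed) {
  set.seed(seed)
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  n_pos <- round(n * cfg$class_ratio)
  y <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  x <- array(0, c(H, W, 3L, n))
  for (i in seq_len(n)) {
    g <- synth_image(H, W, y[i], cfg$texture_gap)
    x[, , 1L, i] <- g; x[, , 2L, i] <- g; x[, , 3L, i] <- g
  }
  list(x = x, y = y)
}

#' Generate a synthetic two-class image dataset
#'
#' Produces seeded grayscale images replicated to three channels, split
#' into disjoint train and test sets, with the configured class imbalance.
#'
#' @param cfg a [synth_config()].
#' @return `list(train = list(x, y), test = list(x, y), config = cfg)`
#'   where `x` is an `(H, W, 3, N)` array in `[0, 1]` and `y` an 0/1
#'   integer label vector (1 = pneumonia-like).
#' @export
generate_synth <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  list(train = synth_split(cfg$n_train, cfg, cfg$seed),
       test = synth_split(cfg$n_test, cfg, cfg$seed + 999983L),
       config = cfg)
}

# nearest-neighbour resize of an (H, W, C) array
resize_nn <- function(img, H, W) {
  d <- dim(img)
  img[round(seq(1, d[1], length.out = H)),
      round(seq(1, d[2], length.out = W)), , drop = FALSE]
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("reading JPEG requires the EBImage package")
    a <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  if (dim(img)[3] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  img[, , 1:3, drop = FALSE]
}

#' Read an image-folder dataset
#'
#' Expects the layout `root/{train,test}/<CLASS>/*.{png,jpg,jpeg}`. Class
#' directory names are mapped to integer labels in alphabetical order (so
#' `NORMAL` = 0, `PNEUMONIA` = 1) and the mapping is reported via a
#' message. Unreadable files are skipped with a warning.
#'
#' @param root dataset root directory.
#' @param image_size optional `c(H, W)`: resize (nearest neighbour) every
#'   image to this size. Required if images differ in size.
#' @return `list(train = list(x, y), test = list(x, y), classes = chr)`.
#' @export
read_imagefolder <- function(root, image_size = NULL) {
  splits <- c("train", "test")
  missing <- splits[!dir.exists(file.path(root, splits))]
  if (length(missing))
    stop("missing split director", if (length(missing) > 1) "ies" else "y",
         " under ", root, ": ", paste(missing, collapse = ", "),
         "; found: ", paste(list.dirs(root, recursive = FALSE,
                                      full.names = FALSE), collapse = ", "),
         call. = FALSE)
  classes <- sort(list.dirs(file.path(root, "train"), recursive = FALSE,
                            full.names = FALSE))
  message("class mapping: ",
          paste(sprintf("%s=%d", classes, seq_along(classes) - 1L),
                collapse = ", "))
  read_split <- function(split) {
    xs <- list(); ys <- integer(); skipped <- 0L
    for (ci in seq_along(classes)) {
      files <- sort(list.files(file.path(root, split, classes[ci]),
                               pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                               full.names = TRUE))
      for (f in files) {
        img <- tryCatch(read_one_image(f), error = function(e) {
          warning("skipping unreadable file ", f, ": ", conditionMessage(e),
                  call. = FALSE)
          NULL
        })
        if (is.null(img)) { skipped <- skipped + 1L; next }
        if (!is.null(image_size))
          img <- resize_nn(img, image_size[1], image_size[2])
        xs[[length(xs) + 1L]] <- img
        ys <- c(ys, ci - 1L)
      }
    }
    if (!length(xs)) stop("no readable images under ", split, call. = FALSE)
    d1 <- dim(xs[[1]])
    if (any(vapply(xs, function(a) !all(dim(a) == d1), logical(1))))
      stop("images differ in size; pass image_size= to resize", call. = FALSE)
    x <- array(0, c(d1, length(xs)))
    for (i in seq_along(xs)) x[, , , i] <- xs[[i]]
    if (skipped) message(split, ": skipped ", skipped, " unreadable file(s)")
    list(x = x, y = ys)
  }
  list(train = read_split("train"), test = read_split("test"),
       classes = classes)
}

#' Write a dataset as an image folder
#'
#' Materializes a dataset (e.g. from [generate_synth()]) as PNG files in
#' the `root/{train,test}/{NORMAL,PNEUMONIA}` layout.
#'
#' @param ds a dataset list with `train` and `test` components.
#' @param root output directory (created if needed).
#' @param class_names directory names for labels 0 and 1.
#' @return `root`, invisibly.
#' @export
write_imagefolder <- function(ds, root,
                              class_names = c("NORMAL", "PNEUMONIA")) {
  for (split in c("train", "test")) {
    d <- ds[[split]]
    for (ci in c(0L, 1L))
      dir.create(file.path(root, split, class_names[ci + 1L]),
                 recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(length(d$y))) {
      img <- d$x[, , , i]
      png::writePNG(img,
                    file.path(root, split, class_names[d$y[i] + 1L],
                              sprintf("img_%05d.png", i)))
    }
  }
  invisible(root)
}
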