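test_that("generation is byte-deterministic and respects the class ratio", {
  cfg <- synth_config(n_train = 24, n_test = 12, image_size = c(16, 16),
                      seed = 9)
  d1 <- generate_synth(cfg)
  d2 <- generate_synth(cfg)
  expect_identical(d1$train$x, d2$train$x)
  expect_identical(d1$test$y, d2$test$y)
  expect_equal(sum(d1$train$y), round(24 * cfg$class_ratio))
  expect_equal(sum(d1$test$y), round(12 * cfg$class_ratio))
  expect_identical(dim(d1$train$x), c(16L, 16L, 3L, 24L))
  expect_true(all(d1$train$x >= 0 & d1$train$x <= 1))
  # the three channels are the replicated grayscale image
  expect_identical(d1$train$x[, , 1, ], d1$train$x[, , 3, ])
  # train and test are drawn from different streams
  expect_false(identical(d1$train$x[, , , 1], d1$test$x[, , , 1]))
  d3 <- generate_synth(synth_config(n_train = 24, n_test = 12,
                                    image_size = c(16, 16), seed = 10))
  expect_false(identical(d1$train$x, d3$train$x))
})

test_that("a zero texture gap makes the classes distributionally alike", {
  d <- generate_synth(synth_config(n_train = 60, n_test = 12,
                                   image_size = c(16, 16), texture_gap = 0,
                                   seed = 5))
  mu <- vapply(seq_along(d$train$y),
               function(i) mean(d$train$x[, , 1, i]), numeric(1))
  gap <- abs(mean(mu[d$train$y == 1]) - mean(mu[d$train$y == 0]))
  expect_lt(gap, 0.03)
  # at full gap the same statistic clearly separates the classes
  d1 <- generate_synth(synth_config(n_train = 60, n_test = 12,
                                    image_size = c(16, 16), texture_gap = 1,
                                    seed = 5))
  mu1 <- vapply(seq_along(d1$train$y),
                function(i) mean(d1$train$x[, , 1, i]), numeric(1))
  expect_gt(abs(mean(mu1[d1$train$y == 1]) - mean(mu1[d1$train$y == 0])),
            0.05)
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(n_train = 0), ">= 1")
  expect_error(synth_config(image_size = c(4, 4)), "image_size")
  expect_error(synth_config(class_ratio = 1), "class_ratio")
  expect_error(synth_config(texture_gap = 2), "texture_gap")
})

test_that("datasets round-trip through the image-folder layout", {
  d <- generate_synth(synth_config(n_train = 8, n_test = 4,
                                   image_size = c(16, 16), seed = 3))
  root <- withr::local_tempdir()
  write_imagefolder(d, root)
  expect_true(dir.exists(file.path(root, "train", "PNEUMONIA")))
  expect_true(dir.exists(file.path(root, "test", "NORMAL")))
  suppressMessages(back <- read_imagefolder(root))
  expect_identical(length(back$train$y), 8L)
  expect_identical(length(back$test$y), 4L)
  expect_identical(back$classes, c("NORMAL", "PNEUMONIA"))
  expect_identical(sum(back$train$y), sum(d$train$y))
  # PNG quantizes to 8 bits; pixels survive within that precision, after
  # accounting for the per-class file ordering
  i1 <- which(d$train$y == 1)[1]
  stored <- back$train$x[, , 1, back$train$y == 1][, , 1]
  expect_lt(min(vapply(seq_len(sum(back$train$y)), function(j)
    max(abs(back$train$x[, , 1, which(back$train$y == 1)[j]] -
              d$train$x[, , 1, i1])), numeric(1))), 1 / 255)
})

test_that("downstream accuracy is monotone in the texture gap on average", {
  gaps <- c(0, 0.5, 1)
  accs <- matrix(NA_real_, length(gaps), 3)
  for (gi in seq_along(gaps)) for (si in 1:3) {
    ds <- generate_synth(synth_config(n_train = 96, n_test = 48,
                                      image_size = c(24, 24),
                                      texture_gap = gaps[gi],
                                      seed = 20 + si))
    g <- build_tiny_resnet(2, c(8L), c(1L), c(3L, 24L, 24L), seed = si)
    fit <- train_model(g, ds$train,
                       small_train_config(epochs = 8, seed = si))
    accs[gi, si] <- evaluate_model(fit$graph, ds$test)$accuracy
  }
  means <- rowMeans(accs)
  # non-decreasing in the gap, with a small slack for seed noise
  expect_true(all(diff(means) > -2))
  expect_gt(means[3], means[1])
})

test_that("missing splits and unreadable files are reported", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "train", "A"), recursive = TRUE)
  expect_error(suppressMessages(read_imagefolder(root)), "test")
  d <- generate_synth(synth_config(n_train = 4, n_test = 2,
                                   image_size = c(16, 16), seed = 3))
  root2 <- withr::local_tempdir()
  write_imagefolder(d, root2)
  writeLines("not a png", file.path(root2, "train", "NORMAL", "junk.png"))
  expect_warning(
    suppressMessages(back <- read_imagefolder(root2)),
    "skipping")
  expect_identical(length(back$train$y), 4L)
})
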