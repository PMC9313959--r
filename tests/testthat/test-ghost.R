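test_that("ghost decomposition of a single convolution has the stated budget", {
  cv <- conv_spec("c", 16, 64, 3, padding = 1, init = FALSE)
  gc1 <- ghostify_conv(cv, ghost_config(s = 2, d = 3))
  expect_identical(n_params(gc1$primary), 3 * 3 * 16 * 32)   # 4608
  expect_identical(n_params(gc1$cheap), 3 * 3 * 32)          # 288
  expect_identical(n_params(gc1), 4896)
  expect_identical(n_params(cv), 9216)
  expect_false(gc1$cheap$has_bias)
  expect_false(gc1$primary$has_bias)
  expect_identical(gc1$cheap$groups, gc1$cheap$c_in)
  # kernel, stride and padding of the replaced convolution are preserved
  cv2 <- conv_spec("c", 8, 16, 3, stride = 2, padding = 1, init = FALSE)
  g2 <- ghostify_conv(cv2, ghost_config(2, 3))
  expect_identical(g2$primary$stride, 2L)
  expect_identical(g2$primary$padding, 1L)
  expect_identical(g2$cheap$stride, 1L)
  expect_error(ghostify_conv(conv_spec("c", 8, 8, 3, groups = 8), ghost_config(2)),
               "degenerate")
  expect_error(ghostify_conv(conv_spec("c", 8, 1, 1), ghost_config(2)),
               "1-channel")
  expect_error(ghost_config(1), ">= 2")
  expect_error(ghost_config(2, 4), "odd")
})

test_that("ghost output shapes equal the replaced convolution's for random shapes", {
  set.seed(31)
  for (i in 1:12) {
    c_in <- sample(2:8, 1)
    c_out <- sample(3:17, 1)          # includes odd widths
    k <- sample(c(1L, 3L), 1)
    stride <- sample(1:2, 1)
    size <- sample(c(8L, 11L, 16L), 1)
    cv <- conv_spec("c", c_in, c_out, k, stride = stride,
                    padding = (k - 1L) %/% 2L)
    gcv <- ghostify_conv(cv, ghost_config(2, 3))
    x <- array(stats::rnorm(size * size * c_in * 2), c(size, size, c_in, 2))
    yd <- cpgnet:::layer_fwd(cv, x)$y
    yg <- cpgnet:::layer_fwd(gcv, x)$y
    expect_identical(dim(yg), dim(yd))
    expect_identical(out_channels(gcv), c_out)
  }
  # ratios above 2 with divisible widths
  g3 <- ghostify_conv(conv_spec("c", 4, 12, 3, padding = 1), ghost_config(3, 3))
  expect_identical(g3$primary$c_out, 4L)
  expect_identical(g3$cheap$c_out, 8L)
  expect_identical(n_params(g3), 3 * 3 * 4 * 4 + 3 * 3 * 8)
})

test_that("an identity cheap kernel reproduces the primary maps exactly", {
  set.seed(17)
  cv <- conv_spec("c", 3, 8, 3, padding = 1)
  gcv <- ghostify_conv(cv, ghost_config(2, 3))
  W <- array(0, dim(gcv$cheap$weights))
  W[, 1, 2, 2] <- 1   # centre tap of the 3x3 depthwise kernel
  gcv$cheap$weights <- W
  x <- array(stats::rnorm(12 * 12 * 3 * 2), c(12, 12, 3, 2))
  y <- cpgnet:::layer_fwd(gcv, x)$y
  yp <- cpgnet:::layer_fwd(gcv$primary, x)$y
  expect_identical(y[, , 1:4, ], yp[, , 1:4, ])
  expect_identical(y[, , 5:8, ], yp)
})

test_that("model-level ghosting replaces only the targeted convolutions", {
  g <- tiny_graph(c(8L, 16L), c(1L, 1L), seed = 6)
  unchanged <- ghostify_model(g, ghost_config(2, 3, target_layers = character()))
  expect_identical(n_params(unchanged), n_params(g))
  one <- ghostify_model(g, ghost_config(2, 3, target_layers = "s1.b1.conv2"))
  expect_s3_class(one$blocks[[1]]$conv2, "ghost_conv")
  expect_s3_class(one$blocks[[1]]$conv1, "conv_spec")
  expect_identical(one$blocks[[1]]$bn2$c, 8L)   # bn width preserved
  gg <- ghostify_model(g, ghost_config(2, 3))
  expect_lt(n_params(gg), n_params(g))
  expect_invisible(validate_graph(gg))
  # per-layer shape-derived closed form matches array sizes everywhere
  for (blk in gg$blocks) for (slot in c("conv1", "conv2", "conv3")) {
    gcv <- blk[[slot]]
    got <- layer_params_ghost(in_channels(gcv), gcv$primary$k_h,
                              gcv$primary$k_w, p_out = gcv$n, s = gcv$s,
                              d = gcv$d)
    expect_identical(as.numeric(got), n_params(gcv) + 0)
  }
  expect_error(ghostify_model(g, ghost_config(2, 3, target_layers = "nope")),
               "not found")
  expect_match(gg$metadata$transforms, "ghost", all = FALSE)
})

test_that("pruning before ghosting leaves fewer channels than the reverse order", {
  g <- tiny_graph(c(8L, 16L), c(1L, 1L), seed = 6)
  rate <- 0.5
  cpg <- compress_model(g, make_plan(g, rate), ghost_config(2, 3))
  for (blk in cpg$blocks) {
    for (slot in c("conv1", "conv2")) {
      n0 <- out_channels(g$blocks[[which(vapply(g$blocks, function(b)
        b$name == blk$name, logical(1)))]][[slot]])
      survivors_prune_first <- out_channels(blk[[slot]])
      # ghost-then-prune arithmetic: only the n0/2 primary maps are
      # prunable, the n0/2 cheap maps always survive
      m <- ceiling(n0 / 2)
      survivors_ghost_first <- (m - round(m * rate)) + (n0 - m)
      expect_lt(survivors_prune_first, survivors_ghost_first)
    }
  }
  expect_identical(cpg$metadata$transforms[1], "prune(rate=0.5)")
  # double identity: zero rate and no ghost targets
  same <- compress_model(g, make_plan(g, 0),
                         ghost_config(2, 3, target_layers = character()))
  expect_identical(n_params(same), n_params(g))
  # pruning a ghosted graph is refused
  gg <- ghostify_model(g, ghost_config(2, 3))
  expect_error(apply_prune(gg, make_plan(g, 0.5)), "ghost")
})

test_that("ghost graphs forward and parameter-reduce every targeted layer", {
  g <- tiny_graph(c(8L, 16L), c(1L, 1L), size = 16L, seed = 6)
  gg <- ghostify_model(g, ghost_config(2, 3))
  x <- rand_input(16L, 2L)
  expect_identical(dim(graph_forward(gg, x)), c(2L, 2L))
  for (blk_pair in Map(list, g$blocks, gg$blocks)) {
    for (slot in c("conv1", "conv2", "conv3")) {
      dense <- blk_pair[[1]][[slot]]
      # reduction is guaranteed exactly when a dense kernel column
      # outweighs one cheap kernel
      if (dense$k_h * dense$k_w * dense$c_in > 9)
        expect_lt(n_params(blk_pair[[2]][[slot]]), n_params(dense))
    }
  }
  expect_identical(n_params(gg), brute_count(unclass(gg)))
})
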