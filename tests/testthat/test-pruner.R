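test_that("channel ranking sorts by ascending scale magnitude with index ties", {
  expect_identical(rank_channels(bn_spec("b", 3, scale = c(0.5, 0.1, 0.9))),
                   c(2L, 1L, 3L))
  # magnitude, not signed value
  expect_identical(rank_channels(bn_spec("b", 3, scale = c(0.3, -0.4, 0.1))),
                   c(3L, 1L, 2L))
  expect_identical(rank_channels(bn_spec("b", 5, scale = rep(0.2, 5))), 1:5)
  set.seed(8)
  for (i in 1:20) {
    sc <- stats::rnorm(sample(3:40, 1))
    expect_identical(rank_channels(bn_spec("b", length(sc), scale = sc)),
                     order(abs(sc), seq_along(sc)))
  }
})

test_that("plans resolve survivor counts with the min-one-channel clamp", {
  g <- tiny_graph(c(16L), c(1L))
  p0 <- make_plan(g, 0)
  expect_identical(length(p0$entries[["s1.b1.conv1"]]$kept), 16L)
  expect_identical(p0$entries[["s1.b1.conv1"]]$kept, 1:16)
  # extreme rate: round(16 * 0.95) = 15 pruned, clamp irrelevant here
  p95 <- make_plan(g, 0.95)
  expect_identical(length(p95$entries[["s1.b1.conv2"]]$kept), 1L)
  # clamp engages when rounding would remove everything
  expect_identical(cpgnet:::kept_count(10L, 0.99), 1L)
  expect_identical(cpgnet:::kept_count(10L, 0.9), 1L)
  expect_identical(cpgnet:::kept_count(64L, 0.9), 6L)
  expect_identical(cpgnet:::kept_count(64L, 0.9, "floor"), 7L)
  expect_error(make_plan(g, 1), "\\[0, 1\\)")
  expect_error(make_plan(g, -0.1), "\\[0, 1\\)")
  expect_error(make_plan(g, c("s1.b1.conv3" = 0.5)), "dimension-matching")
  expect_error(make_plan(g, c("stem.conv" = 0.5)), "not prunable")
})

test_that("kept sets equal the brute-force k-largest-magnitude oracle", {
  set.seed(21)
  for (i in 1:20) {
    w <- sample(c(4L, 8L, 12L, 16L), sample(1:2, 1), replace = TRUE)
    g <- tiny_graph(w, rep(1L, length(w)), seed = i)
    # randomize the scales so the ranking is non-trivial
    for (j in seq_along(g$blocks)) {
      g$blocks[[j]]$bn1$scale <- stats::rnorm(g$blocks[[j]]$bn1$c)
      g$blocks[[j]]$bn2$scale <- stats::rnorm(g$blocks[[j]]$bn2$c)
    }
    rate <- stats::runif(1, 0, 0.9)
    plan <- make_plan(g, rate)
    for (blk in g$blocks) {
      for (slot in c(1, 2)) {
        e <- plan$entries[[paste0(blk$name, ".conv", slot)]]
        bn <- blk[[paste0("bn", slot)]]
        expect_identical(e$kept, oracle_kept(bn$scale, length(e$kept)))
      }
    }
  }
})

test_that("pruning surgery preserves structure and is a no-op at rate zero", {
  g <- tiny_graph(c(8L, 16L), c(1L, 1L), seed = 4)
  p0 <- apply_prune(g, make_plan(g, 0))
  expect_identical(n_params(p0), n_params(g))
  p <- apply_prune(g, make_plan(g, 0.5))
  expect_invisible(validate_graph(p))
  # original untouched
  expect_identical(g$blocks[[1]]$conv1$c_out, 8L)
  expect_identical(p$blocks[[1]]$conv1$c_out, 4L)
  # conv3 and downsample widths preserved
  expect_identical(out_channels(p$blocks[[1]]$conv3),
                   out_channels(g$blocks[[1]]$conv3))
  expect_identical(p$blocks[[1]]$downsample$conv$c_out,
                   g$blocks[[1]]$downsample$conv$c_out)
  # forward still emits logits even at an extreme rate
  px <- apply_prune(g, make_plan(g, 0.95))
  expect_identical(dim(graph_forward(px, rand_input(16L, 2L))), c(2L, 2L))
  expect_match(p$metadata$transforms, "prune", all = FALSE)
})

test_that("parameter totals are non-increasing in the pruning rate", {
  g <- tiny_graph(c(8L, 16L), c(2L, 1L), seed = 9)
  totals <- vapply(c(0, 0.1, 0.25, 0.5, 0.75, 0.9),
                   function(r) n_params(apply_prune(g, make_plan(g, r))),
                   numeric(1))
  expect_true(all(diff(totals) <= 0))
  # and per-layer monotonicity in a single layer's rate
  one <- vapply(c(0, 0.3, 0.6, 0.9), function(r)
    n_params(apply_prune(g, make_plan(g, c("s2.b1.conv2" = r)))), numeric(1))
  expect_true(all(diff(one) < 0))
})

test_that("removing exactly-zero channels is output-preserving", {
  g <- tiny_graph(c(8L, 16L), c(1L, 1L), size = 16L, seed = 12)
  zap1 <- c(2L, 5L, 7L)
  g$blocks[[1]]$bn1$scale[zap1] <- 0
  g$blocks[[1]]$bn1$shift[zap1] <- 0
  zap2 <- c(1L, 4L)
  g$blocks[[2]]$bn2$scale[zap2] <- 0
  g$blocks[[2]]$bn2$shift[zap2] <- 0
  plan <- make_plan(g, list("s1.b1.conv1" = 3 / 8, "s2.b1.conv2" = 2 / 16))
  expect_identical(plan$entries[["s1.b1.conv1"]]$kept, setdiff(1:8, zap1))
  p <- apply_prune(g, plan)
  x <- rand_input(16L, 3L, seed = 5)
  expect_lt(max(abs(graph_forward(g, x) - graph_forward(p, x))), 1e-12)
})

test_that("the sparsity penalty adds gamma times the scale L1 norm", {
  expect_identical(sparsity_loss(1, c(0.5, -0.5), gamma = 0), 1)
  expect_equal(sparsity_loss(1, c(0.5, -0.5), gamma = 0.1), 1.1)
  expect_identical(sparsity_loss(0, numeric(0), gamma = 1), 0)
  expect_error(sparsity_loss(1, 1, gamma = -1), ">= 0")
})

test_that("plans round-trip through YAML", {
  g <- tiny_graph(c(8L, 16L), c(1L, 1L), seed = 4)
  plan <- make_plan(g, 0.5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_plan(plan, path)
  plan2 <- read_plan(path)
  expect_identical(lapply(plan2$entries, `[[`, "kept"),
                   lapply(plan$entries, `[[`, "kept"))
  expect_identical(n_params(apply_prune(g, plan2)),
                   n_params(apply_prune(g, plan)))
  # a plan naming layers the graph lacks is rejected
  g2 <- tiny_graph(c(8L), c(1L))
  expect_error(apply_prune(g2, plan), "absent")
})
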