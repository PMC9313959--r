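test_that("classification metrics match hand-counted confusion tables", {
  m <- classification_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0), 2)
  expect_identical(m$accuracy, 75)
  expect_identical(unname(m$confusion_matrix), rbind(c(2L, 1L), c(0L, 1L)))
  expect_identical(m$n_eval, 4L)
  expect_identical(sum(m$confusion_matrix), m$n_eval)
  # row sums are label counts, column sums are prediction counts
  expect_identical(unname(rowSums(m$confusion_matrix)), c(3, 1))
  expect_identical(unname(colSums(m$confusion_matrix)), c(2, 2))
  perfect <- classification_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1), 2)
  expect_identical(unname(perfect$precision), c(1, 1))
  expect_identical(unname(perfect$recall), c(1, 1))
  lazy <- classification_metrics(rep(1, 4), c(0, 0, 1, 1), 2)
  expect_identical(lazy$accuracy, 50)
  expect_identical(unname(lazy$recall), c(0, 1))
  expect_true(is.nan(lazy$precision[[1]]))   # class never predicted
  expect_error(classification_metrics(integer(), integer(), 2), "empty")
})

test_that("a zero learning rate leaves the weights untouched", {
  g <- tiny_graph(c(8L), c(1L), size = 16L, seed = 3)
  ds <- generate_synth(synth_config(n_train = 16, n_test = 8,
                                    image_size = c(16, 16), seed = 2))
  fit <- train_model(g, ds$train, small_train_config(epochs = 1, lr = 0))
  expect_identical(cpgnet:::params_tree(fit$graph), cpgnet:::params_tree(g))
  expect_identical(nrow(fit$history), 1L)
})

test_that("training is bit-reproducible from its seed", {
  g <- tiny_graph(c(8L), c(1L), size = 16L, seed = 3)
  ds <- generate_synth(synth_config(n_train = 32, n_test = 8,
                                    image_size = c(16, 16), seed = 2))
  cfg7 <- small_train_config(epochs = 2, seed = 7)
  cfg7$batch_size <- 8L   # several batches, so the shuffle matters
  f1 <- train_model(g, ds$train, cfg7)
  f2 <- train_model(g, ds$train, cfg7)
  expect_identical(f1$history, f2$history)
  expect_identical(cpgnet:::params_tree(f1$graph),
                   cpgnet:::params_tree(f2$graph))
  expect_true(all(is.finite(f1$history$loss)))
  cfg8 <- cfg7
  cfg8$seed <- 8L
  f3 <- train_model(g, ds$train, cfg8)
  expect_false(identical(f1$history$loss, f3$history$loss))
})

test_that("input validation rejects bad labels and empty data", {
  g <- tiny_graph(c(8L), c(1L), size = 16L)
  ds <- generate_synth(synth_config(n_train = 8, n_test = 4,
                                    image_size = c(16, 16), seed = 1))
  bad <- ds$train
  bad$y[1] <- 5L
  expect_error(train_model(g, bad, small_train_config(1)), "labels")
  expect_error(train_model(g, list(x = NULL, y = integer()),
                           small_train_config(1)), "empty")
})

test_that("the learning-rate schedule decays stepwise", {
  cfg <- train_config(epochs = 10, lr = 0.1, lr_steps = c(0.5, 0.75),
                      lr_decay = 0.1)
  lrs <- vapply(1:10, function(e) cpgnet:::lr_at_epoch(cfg, e), numeric(1))
  expect_identical(lrs[1], 0.1)
  expect_equal(lrs[6], 0.01)
  expect_equal(lrs[8], 0.001)
})

test_that("a tiny net learns the separable synthetic task", {
  ds <- generate_synth(synth_config(n_train = 128, n_test = 64,
                                    image_size = c(28, 28), texture_gap = 1,
                                    seed = 21))
  g <- build_tiny_resnet(2, c(8L), c(1L), c(3L, 28L, 28L), seed = 1)
  fit <- train_model(g, ds$train, small_train_config(epochs = 8))
  m <- evaluate_model(fit$graph, ds$test)
  expect_gte(m$accuracy, 95)
  expect_identical(sum(m$confusion_matrix), 64L)
  # the loss actually decreased
  expect_lt(utils::tail(fit$history$loss, 1), fit$history$loss[1])
})

test_that("the L1 scale penalty shrinks batch-norm scales", {
  ds <- generate_synth(synth_config(n_train = 32, n_test = 8,
                                    image_size = c(16, 16), seed = 3))
  g <- tiny_graph(c(8L), c(1L), size = 16L, seed = 5)
  plain <- train_model(g, ds$train, small_train_config(epochs = 3, seed = 2))
  sparse <- train_model(g, ds$train,
                        small_train_config(epochs = 3, seed = 2,
                                           sparsity = list(gamma = 0.05)))
  expect_lt(sum(abs(all_bn_scales(sparse$graph))),
            sum(abs(all_bn_scales(plain$graph))))
})

test_that("zero-epoch fine-tuning returns the compressed model unchanged", {
  g <- tiny_graph(c(8L), c(1L), size = 16L, seed = 5)
  comp <- compress_model(g, make_plan(g, 0.5), ghost_config(2, 3))
  ds <- generate_synth(synth_config(n_train = 16, n_test = 8,
                                    image_size = c(16, 16), seed = 4))
  ft <- finetune_after_compress(comp, ds$train,
                                small_train_config(epochs = 0),
                                eval_data = ds$test)
  expect_identical(ft$pre_metrics$accuracy, ft$post_metrics$accuracy)
  expect_identical(cpgnet:::params_tree(ft$graph),
                   cpgnet:::params_tree(comp))
  # fine-tuning requires compression provenance
  expect_error(finetune_after_compress(g, ds$train, small_train_config(0)),
               "provenance")
})

test_that("repeated runs average their seeded evaluation accuracies", {
  g <- tiny_graph(c(8L), c(1L), size = 16L, seed = 5)
  ds <- generate_synth(synth_config(n_train = 24, n_test = 16,
                                    image_size = c(16, 16), seed = 4))
  cfg <- small_train_config(epochs = 1, seed = 3)
  cfg$repeats <- 2L
  rep2 <- train_repeated(g, ds$train, cfg, ds$test)
  expect_length(rep2$accuracies, 2L)
  expect_identical(rep2$mean_accuracy, mean(rep2$accuracies))
})
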