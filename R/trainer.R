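# Mini-batch SGD training, fine-tuning and evaluation for bottleneck
# graphs. The engine is pure R (im2col + BLAS) and intended for the
# desk-scale regime: tiny networks, small images, tens of epochs. The full
# 190-epoch protocol is reachable through the same configuration object but
# never required by anything in this package.

#' Training configuration
#'
#' @param epochs number of passes over the training set.
#' @param batch_size mini-batch size.
#' @param lr initial learning rate, decayed stepwise by `lr_decay` at the
#'   epochs given (as fractions) in `lr_steps`.
#' @param momentum,weight_decay SGD momentum and L2 weight decay.
#' @param repeats number of independently seeded runs whose evaluation
#'   metrics are averaged by [train_repeated()].
#' @param seed integer seed; fixes shuffling, augmentation and hence the
#'   entire loss history.
#' @param sparsity optional `list(gamma = )`: adds an L1 penalty
#'   `gamma * sum(|bn scales|)` to the loss (the sparsity-trained slimming
#'   baseline objective).
#' @param lr_steps,lr_decay step-decay schedule: the learning rate is
#'   multiplied by `lr_decay` when training passes each fraction of
#'   `epochs`.
#' @param augment random-crop (zero padding `crop_pad`) and horizontal-flip
#'   augmentation during training.
#' @param crop_pad padding in pixels for the random crop.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 190L, batch_size = 32L, lr = 0.1,
                         momentum = 0.9, weight_decay = 1e-4, repeats = 5L,
                         seed = 1L, sparsity = NULL,
                         lr_steps = c(0.5, 0.75), lr_decay = 0.1,
                         augment = TRUE, crop_pad = 4L) {
  if (epochs < 0L || batch_size < 1L || repeats < 1L)
    stop("epochs must be >= 0, batch_size and repeats >= 1", call. = FALSE)
  if (lr < 0) stop("lr must be >= 0", call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, weight_decay = weight_decay,
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 sparsity = sparsity, lr_steps = lr_steps,
                 lr_decay = lr_decay, augment = isTRUE(augment),
                 crop_pad = as.integer(crop_pad)),
            class = "train_config")
}

check_data <- function(data, graph) {
  if (is.null(data$x) || is.null(data$y) || length(data$y) == 0L)
    stop("empty dataset", call. = FALSE)
  d <- dim(data$x)
  if (length(d) != 4L || d[4] != length(data$y))
    stop("data$x must be (H, W, C, N) with N matching length(data$y)",
         call. = FALSE)
  if (d[3] != graph$input_shape[1])
    stop("data channels do not match the graph input shape", call. = FALSE)
  k <- graph$head$num_classes
  if (any(data$y < 0L | data$y >= k))
    stop("labels must lie in [0, ", k, ")", call. = FALSE)
  invisible(TRUE)
}

augment_batch <- function(xb, pad) {
  d <- dim(xb)
  for (i in seq_len(d[4])) {
    if (stats::runif(1) < 0.5)
      xb[, , , i] <- xb[, rev(seq_len(d[2])), , i]
    if (pad > 0L) {
      dy <- sample.int(2L * pad + 1L, 1L) - pad - 1L
      dx <- sample.int(2L * pad + 1L, 1L) - pad - 1L
      if (dy != 0L || dx != 0L) {
        img <- array(0, d[1:3])
        src_r <- pmax(1L, 1L - dy):pmin(d[1], d[1] - dy)
        src_c <- pmax(1L, 1L - dx):pmin(d[2], d[2] - dx)
        img[src_r + dy, src_c + dx, ] <- xb[src_r, src_c, , i]
        xb[, , , i] <- img
      }
    }
  }
  xb
}

lr_at_epoch <- function(cfg, epoch) {
  boundaries <- floor(cfg$lr_steps * cfg$epochs)
  cfg$lr * cfg$lr_decay^sum(epoch > boundaries)
}

add_sparsity_grads <- function(g, graph, gamma) {
  sg <- function(bn_grad, bn) {
    bn_grad$scale <- bn_grad$scale + gamma * sign(bn$scale)
    bn_grad
  }
  g$stem$bn <- sg(g$stem$bn, graph$stem$bn)
  for (i in seq_along(graph$blocks)) {
    blk <- graph$blocks[[i]]
    g$blocks[[i]]$bn1 <- sg(g$blocks[[i]]$bn1, blk$bn1)
    g$blocks[[i]]$bn2 <- sg(g$blocks[[i]]$bn2, blk$bn2)
    g$blocks[[i]]$bn3 <- sg(g$blocks[[i]]$bn3, blk$bn3)
    if (!is.null(blk$downsample))
      g$blocks[[i]]$downsample$bn <- sg(g$blocks[[i]]$downsample$bn,
                                        blk$downsample$bn)
  }
  g
}

#' Train a classifier graph
#'
#' Mini-batch SGD on softmax cross-entropy (plus the optional L1
#' batch-norm-scale penalty), with momentum, weight decay, step learning
#' rate decay and optional crop/flip augmentation. Deterministic given
#' `cfg$seed` and the data: two identical calls produce bit-identical loss
#' histories and weights.
#'
#' @param graph a bottleneck-family `model_graph` with weights.
#' @param data `list(x = (H, W, C, N) array, y = 0-based labels)`.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch loss.
#' @return `list(graph = trained graph, history = data.frame(epoch, loss,
#'   lr), config = cfg)`.
#' @export
train_model <- function(graph, data, cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  check_data(data, graph)
  set.seed(cfg$seed)
  n <- length(data$y)
  vel <- NULL
  history <- data.frame(epoch = integer(), loss = numeric(), lr = numeric())
  gamma <- if (!is.null(cfg$sparsity)) cfg$sparsity$gamma else 0
  for (ep in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(cfg, ep)
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- data$x[, , , idx, drop = FALSE]
      yb <- data$y[idx]
      if (cfg$augment) xb <- augment_batch(xb, cfg$crop_pad)
      fw <- graph_fwd(graph, xb, train = TRUE, keep = TRUE)
      graph <- fw$graph
      ce <- softmax_ce(fw$logits, yb)
      loss <- ce$loss
      if (gamma > 0) loss <- sparsity_loss(loss, all_bn_scales(graph), gamma)
      if (!is.finite(loss))
        stop("non-finite loss at epoch ", ep, "; lower the learning rate",
             call. = FALSE)
      g <- graph_bwd(graph, fw$cache, ce$dlogits)
      if (gamma > 0) g <- add_sparsity_grads(g, graph, gamma)
      p <- params_tree(graph)
      if (cfg$weight_decay > 0)
        g <- tree_map2(function(gi, pi) gi + cfg$weight_decay * pi, g, p)
      vel <- if (is.null(vel)) g
             else tree_map2(function(v, gi) cfg$momentum * v + gi, vel, g)
      p <- tree_map2(function(pi, v) pi - lr * v, p, vel)
      graph <- graph_set_params(graph, p)
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loss = ep_loss / nb, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  lr %.4g", ep, ep_loss / nb, lr))
  }
  list(graph = graph, history = history, config = cfg)
}

#' Fine-tune a compressed graph
#'
#' The same loop as [train_model()], intended for short post-surgery
#' recovery. The graph must carry compression provenance in
#' `metadata$transforms`. When `eval_data` is supplied, evaluation metrics
#' before and after fine-tuning are returned so recovery can be quantified.
#' With `epochs = 0` the graph (and hence its metrics) is returned
#' unchanged.
#'
#' @inheritParams train_model
#' @param eval_data optional labeled evaluation set.
#' @return as [train_model()], plus `pre_metrics` / `post_metrics` when
#'   `eval_data` is given.
#' @export
finetune_after_compress <- function(graph, data, cfg, eval_data = NULL,
                                    verbose = FALSE) {
  if (!length(graph$metadata$transforms))
    stop("graph carries no compression provenance; use train_model() for ",
         "uncompressed training", call. = FALSE)
  pre <- if (!is.null(eval_data)) evaluate_model(graph, eval_data)
  out <- train_model(graph, data, cfg, verbose = verbose)
  if (!is.null(eval_data)) {
    out$pre_metrics <- pre
    out$post_metrics <- evaluate_model(out$graph, eval_data)
  }
  out
}

#' Train several independently seeded runs and average the metrics
#'
#' Runs `cfg$repeats` trainings with seeds `cfg$seed + 0 .. repeats - 1`
#' and reports each run's evaluation accuracy together with their mean.
#'
#' @inheritParams train_model
#' @param eval_data labeled evaluation set.
#' @return `list(runs = list of train_model results, accuracies = numeric,
#'   mean_accuracy = numeric)`.
#' @export
train_repeated <- function(graph, data, cfg, eval_data) {
  runs <- vector("list", cfg$repeats)
  accs <- numeric(cfg$repeats)
  for (r in seq_len(cfg$repeats)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1L
    runs[[r]] <- train_model(graph, data, cfg_r)
    accs[r] <- evaluate_model(runs[[r]]$graph, eval_data)$accuracy
  }
  list(runs = runs, accuracies = accs, mean_accuracy = mean(accs))
}

#' Classification metrics from predictions
#'
#' @param pred,truth 0-based integer vectors of equal length.
#' @param num_classes number of classes `k`.
#' @return an object of class `metrics`: accuracy (percent), `k x k`
#'   confusion matrix (rows = actual, columns = predicted), per-class
#'   precision and recall, and `n_eval`.
#' @examples
#' classification_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0), 2)$accuracy  # 75
#' @export
classification_metrics <- function(pred, truth, num_classes) {
  if (!length(truth)) stop("empty evaluation set", call. = FALSE)
  lv <- 0:(num_classes - 1L)
  cm <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  cm <- matrix(as.integer(cm), num_classes, num_classes,
               dimnames = list(actual = lv, predicted = lv))
  precision <- diag(cm) / colSums(cm)
  recall <- diag(cm) / rowSums(cm)
  structure(list(accuracy = 100 * sum(diag(cm)) / length(truth),
                 confusion_matrix = cm, precision = precision,
                 recall = recall, n_eval = length(truth)),
            class = "metrics")
}

#' @export
print.metrics <- function(x, ...) {
  cat(sprintf("<metrics> accuracy %.2f%% on %d samples\n", x$accuracy,
              x$n_eval))
  print(x$confusion_matrix)
  cat("precision:", sprintf("%.3f", x$precision), "\n")
  cat("recall:   ", sprintf("%.3f", x$recall), "\n")
  invisible(x)
}

#' Evaluate a graph on labeled data
#'
#' Forward passes in evaluation mode (running batch-norm statistics),
#' argmax prediction, and [classification_metrics()]. Class order is fixed
#' by the label coding (0 = normal, 1 = pneumonia for the synthetic data).
#'
#' @param graph a bottleneck-family `model_graph`.
#' @param data `list(x, y)` evaluation set.
#' @param batch_size forward batch size.
#' @return a `metrics` object.
#' @export
evaluate_model <- function(graph, data, batch_size = 64L) {
  check_data(data, graph)
  n <- length(data$y)
  pred <- integer(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    logits <- graph_forward(graph, data$x[, , , idx, drop = FALSE])
    pred[idx] <- max.col(t(logits)) - 1L
  }
  classification_metrics(pred, data$y, graph$head$num_classes)
}
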