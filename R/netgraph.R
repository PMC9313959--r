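# Core data model: convolution, batch-norm, bottleneck and whole-model
# specifications.  Everything the surgery, accounting and training code acts
# on is one of these plain-list S3 objects.

#' He-uniform weight initializer
#'
#' Draws from U(-b, b) with b = sqrt(6 / fan_in), the standard initialization
#' for ReLU networks. Consumes the current R random stream.
#'
#' @param dims integer vector of array dimensions.
#' @param fan_in number of input connections per output unit.
#' @return numeric array of dimension `dims`.
#' @keywords internal
he_uniform <- function(dims, fan_in) {
  b <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -b, b), dim = dims)
}

#' Convolution layer specification
#'
#' Describes a (possibly grouped) 2-D convolution. Weights are stored as a
#' 4-D array of dimension `c_out x c_in/groups x k_h x k_w`. Convolutions
#' followed by batch normalization are conventionally bias-free.
#'
#' @param name layer identifier (used by pruning plans and reports).
#' @param c_in,c_out input/output channel counts.
#' @param k_h,k_w kernel height and width in pixels.
#' @param stride,padding spatial stride and zero padding.
#' @param groups number of channel groups; `1` is a dense convolution,
#'   `c_in` a depthwise one. Must divide both `c_in` and `c_out`.
#' @param has_bias whether the layer has a per-output-channel bias.
#' @param weights,bias optional pre-set parameter arrays.
#' @param init if `TRUE` and no weights given, initialize He-uniform from the
#'   current RNG stream; if `FALSE`, leave weights `NULL` (shape-only spec).
#' @return an object of class `conv_spec`.
#' @export
conv_spec <- function(name, c_in, c_out, k_h, k_w = k_h, stride = 1L,
                      padding = 0L, groups = 1L, has_bias = FALSE,
                      weights = NULL, bias = NULL, init = TRUE) {
  c_in <- as.integer(c_in); c_out <- as.integer(c_out)
  k_h <- as.integer(k_h); k_w <- as.integer(k_w)
  groups <- as.integer(groups)
  if (c_in < 1L || c_out < 1L || k_h < 1L || k_w < 1L)
    stop("conv_spec '", name, "': channel and kernel sizes must be >= 1",
         call. = FALSE)
  if (c_in %% groups != 0L || c_out %% groups != 0L)
    stop("conv_spec '", name, "': groups must divide both c_in and c_out",
         call. = FALSE)
  dims <- c(c_out, c_in %/% groups, k_h, k_w)
  if (is.null(weights) && init)
    weights <- he_uniform(dims, fan_in = dims[2] * k_h * k_w)
  if (!is.null(weights) && !all(dim(weights) == dims))
    stop("conv_spec '", name, "': weight array shape does not match fields",
         call. = FALSE)
  if (has_bias && is.null(bias)) bias <- numeric(c_out)
  if (!has_bias) bias <- NULL
  structure(
    list(name = name, c_in = c_in, c_out = c_out, k_h = k_h, k_w = k_w,
         stride = as.integer(stride), padding = as.integer(padding),
         groups = groups, has_bias = has_bias, weights = weights,
         bias = bias),
    class = "conv_spec")
}

#' Batch-normalization layer specification
#'
#' Per-channel affine batch normalization
#' `y = scale * (x - mean) / sqrt(sd^2 + eps) + shift`. The `scale` vector is
#' the channel-importance score used by the pruner; `mean`/`sd` are running
#' statistics (not trainable, not counted as parameters).
#'
#' @param name layer identifier.
#' @param c channel count.
#' @param scale,shift trainable per-channel affine parameters.
#' @param mean,sd running statistics used at evaluation time.
#' @param eps numerical stabilizer added to the variance.
#' @return an object of class `bn_spec`.
#' @export
bn_spec <- function(name, c, scale = rep(1, c), shift = rep(0, c),
                    mean = rep(0, c), sd = rep(1, c), eps = 1e-5) {
  c <- as.integer(c)
  if (c < 1L) stop("bn_spec '", name, "': c must be >= 1", call. = FALSE)
  lens <- c(length(scale), length(shift), length(mean), length(sd))
  if (!all(lens == c))
    stop("bn_spec '", name, "': all parameter vectors must have length c",
         call. = FALSE)
  if (any(sd < 0) || eps <= 0)
    stop("bn_spec '", name, "': sd must be >= 0 and eps > 0", call. = FALSE)
  structure(list(name = name, c = c, scale = as.numeric(scale),
                 shift = as.numeric(shift), mean = as.numeric(mean),
                 sd = as.numeric(sd), eps = eps),
            class = "bn_spec")
}

#' Bottleneck residual block specification
#'
#' The three-convolution residual unit (1x1 reduce, 3x3, 1x1 expand), each
#' convolution followed by batch normalization, with an optional projection
#' (downsample) convolution on the shortcut. Only `conv1` and `conv2` are
#' ever pruned, so the block's output width -- which must match the shortcut
#' -- is never disturbed.
#'
#' @param name block identifier, used as prefix for its layers.
#' @param conv1,conv2,conv3 `conv_spec` (or `ghost_conv`) objects.
#' @param bn1,bn2,bn3 matching `bn_spec` objects.
#' @param downsample optional `list(conv = , bn = )` for the shortcut.
#' @return an object of class `bottleneck`.
#' @export
bottleneck_spec <- function(name, conv1, bn1, conv2, bn2, conv3, bn3,
                            downsample = NULL) {
  blk <- structure(
    list(name = name, conv1 = conv1, bn1 = bn1, conv2 = conv2, bn2 = bn2,
         conv3 = conv3, bn3 = bn3, downsample = downsample),
    class = "bottleneck")
  validate_bottleneck(blk)
  blk
}

validate_bottleneck <- function(blk) {
  if (out_channels(blk$conv1) != blk$bn1$c ||
      out_channels(blk$conv1) != in_channels(blk$conv2))
    stop("bottleneck '", blk$name, "': conv1/bn1/conv2 channels do not chain",
         call. = FALSE)
  if (out_channels(blk$conv2) != blk$bn2$c ||
      out_channels(blk$conv2) != in_channels(blk$conv3))
    stop("bottleneck '", blk$name, "': conv2/bn2/conv3 channels do not chain",
         call. = FALSE)
  if (out_channels(blk$conv3) != blk$bn3$c)
    stop("bottleneck '", blk$name, "': conv3/bn3 channels do not chain",
         call. = FALSE)
  if (!is.null(blk$downsample)) {
    if (out_channels(blk$downsample$conv) != out_channels(blk$conv3))
      stop("bottleneck '", blk$name,
           "': downsample output must match conv3 output", call. = FALSE)
    if (out_channels(blk$downsample$conv) != blk$downsample$bn$c)
      stop("bottleneck '", blk$name, "': downsample conv/bn mismatch",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Channel-count accessors
#'
#' Output/input channel count of a layer specification; ghost modules report
#' their total (primary + cheap) output width.
#'
#' @param spec a `conv_spec` or `ghost_conv`.
#' @return integer channel count.
#' @export
out_channels <- function(spec) UseMethod("out_channels")
#' @export
out_channels.conv_spec <- function(spec) spec$c_out
#' @export
out_channels.ghost_conv <- function(spec) spec$n

#' @rdname out_channels
#' @export
in_channels <- function(spec) UseMethod("in_channels")
#' @export
in_channels.conv_spec <- function(spec) spec$c_in
#' @export
in_channels.ghost_conv <- function(spec) spec$primary$c_in

#' Model graph
#'
#' Ordered description of a convolutional classifier. Two families exist:
#' `"bottleneck"` graphs (stem conv/bn, optional stem max-pool, a list of
#' [bottleneck_spec()] blocks, global average pool and a linear head) which
#' support the full forward/backward engine and all surgery, and `"flat"`
#' graphs (an ordered layer row list with precomputed output spatial sizes)
#' used for the reference architectures that only ever feed the accounting
#' module.
#'
#' @param family `"bottleneck"` or `"flat"`.
#' @param stem `list(conv = , bn = )` for bottleneck graphs.
#' @param stem_pool logical: 3x3/2 max pool after the stem.
#' @param blocks list of `bottleneck` objects.
#' @param layers flat row list (flat family only).
#' @param head `list(in_features, num_classes, W, b)`.
#' @param input_shape `c(channels, height, width)`.
#' @param final_hw spatial size entering the global pool (flat family).
#' @param metadata free-form list; `metadata$transforms` records applied
#'   surgery for provenance.
#' @return an object of class `model_graph`.
#' @export
model_graph <- function(family, stem = NULL, stem_pool = FALSE, blocks = NULL,
                        layers = NULL, head, input_shape, final_hw = NULL,
                        metadata = list()) {
  if (is.null(metadata$transforms)) metadata$transforms <- character()
  structure(
    list(family = family, stem = stem, stem_pool = stem_pool, blocks = blocks,
         layers = layers, head = head, input_shape = as.integer(input_shape),
         final_hw = final_hw, metadata = metadata),
    class = "model_graph")
}

make_head <- function(in_features, num_classes, init = TRUE) {
  W <- if (init) he_uniform(c(num_classes, in_features), in_features) else NULL
  list(in_features = as.integer(in_features),
       num_classes = as.integer(num_classes),
       W = W, b = numeric(num_classes))
}

#' Validate a model graph
#'
#' Checks that adjacent layers' channel counts chain consistently end to end
#' and that every weight array matches its declared shape. Errors on the
#' first violation; returns the graph invisibly otherwise.
#'
#' @param graph a `model_graph`.
#' @return the graph, invisibly.
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "model_graph"))
  if (length(graph$input_shape) != 3L || any(graph$input_shape <= 0L))
    stop("input_shape must be three positive integers", call. = FALSE)
  if (graph$family == "bottleneck") {
    if (graph$stem$conv$c_in != graph$input_shape[1])
      stop("stem input channels do not match input_shape", call. = FALSE)
    if (graph$stem$conv$c_out != graph$stem$bn$c)
      stop("stem conv/bn channel mismatch", call. = FALSE)
    prev <- graph$stem$conv$c_out
    for (blk in graph$blocks) {
      validate_bottleneck(blk)
      if (in_channels(blk$conv1) != prev)
        stop("block '", blk$name, "' input does not chain (expected ",
             in_channels(blk$conv1), ", got ", prev, ")", call. = FALSE)
      if (!is.null(blk$downsample) &&
          in_channels(blk$downsample$conv) != prev)
        stop("block '", blk$name, "' downsample input does not chain",
             call. = FALSE)
      if (is.null(blk$downsample) && out_channels(blk$conv3) != prev)
        stop("block '", blk$name,
             "' identity shortcut requires matching widths", call. = FALSE)
      prev <- out_channels(blk$conv3)
    }
    if (graph$head$in_features != prev)
      stop("head in_features does not match final block output", call. = FALSE)
  } else {
    for (row in graph$layers) {
      if (row$kind == "conv") check_conv_weights(row$spec)
    }
  }
  for (cv in all_conv_specs(graph)) check_conv_weights(cv)
  invisible(graph)
}

check_conv_weights <- function(spec) {
  if (inherits(spec, "ghost_conv")) {
    check_conv_weights(spec$primary)
    check_conv_weights(spec$cheap)
    return(invisible(TRUE))
  }
  if (!is.null(spec$weights)) {
    dims <- c(spec$c_out, spec$c_in %/% spec$groups, spec$k_h, spec$k_w)
    if (!all(dim(spec$weights) == dims))
      stop("conv '", spec$name, "': weight shape inconsistent with fields",
           call. = FALSE)
  }
  invisible(TRUE)
}

# All convolution specs of a graph, in order, as a flat list.
all_conv_specs <- function(graph) {
  out <- list()
  if (graph$family == "bottleneck") {
    out <- c(out, list(graph$stem$conv))
    for (blk in graph$blocks) {
      out <- c(out, list(blk$conv1, blk$conv2, blk$conv3))
      if (!is.null(blk$downsample)) out <- c(out, list(blk$downsample$conv))
    }
  } else {
    for (row in graph$layers) if (row$kind == "conv")
      out <- c(out, list(row$spec))
  }
  out
}

#' Count trainable parameters
#'
#' Sums the sizes of every trainable parameter array: convolution weights
#' (and biases where present), the per-channel batch-norm scale and shift
#' pairs, and the linear head. Running batch-norm statistics are not
#' trainable and are not counted.
#'
#' @param x a spec object or a `model_graph`.
#' @return integer-valued numeric count.
#' @export
n_params <- function(x) UseMethod("n_params")

#' @export
n_params.conv_spec <- function(x)
  x$c_out * (x$c_in %/% x$groups) * x$k_h * x$k_w + if (x$has_bias) x$c_out else 0

#' @export
n_params.bn_spec <- function(x) 2 * x$c

#' @export
n_params.ghost_conv <- function(x) n_params(x$primary) + n_params(x$cheap)

#' @export
n_params.bottleneck <- function(x) {
  p <- n_params(x$conv1) + n_params(x$bn1) + n_params(x$conv2) +
    n_params(x$bn2) + n_params(x$conv3) + n_params(x$bn3)
  if (!is.null(x$downsample))
    p <- p + n_params(x$downsample$conv) + n_params(x$downsample$bn)
  p
}

#' @export
n_params.model_graph <- function(x) {
  p <- x$head$in_features * x$head$num_classes + x$head$num_classes
  if (x$family == "bottleneck") {
    p <- p + n_params(x$stem$conv) + n_params(x$stem$bn)
    for (blk in x$blocks) p <- p + n_params(blk)
  } else {
    for (row in x$layers)
      if (row$kind %in% c("conv", "bn")) p <- p + n_params(row$spec)
  }
  p
}

#' @export
print.model_graph <- function(x, ...) {
  nconv <- length(all_conv_specs(x))
  cat("<model_graph> ", x$metadata$name %||% "unnamed",
      "  [", x$family, "]\n", sep = "")
  cat("  input ", paste(x$input_shape, collapse = "x"),
      ", ", if (x$family == "bottleneck") length(x$blocks) else NA_integer_,
      " blocks, ", nconv, " convolution layers\n", sep = "")
  cat("  classes: ", x$head$num_classes,
      ", trainable parameters: ", format(n_params(x), big.mark = ","),
      "\n", sep = "")
  if (length(x$metadata$transforms))
    cat("  transforms: ", paste(x$metadata$transforms, collapse = " -> "),
        "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
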