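# Builders for the bottleneck architectures the package compresses: the
# full ResNet50 classifier and a miniature, structurally homologous network
# for fast desk-scale experiments and tests.

make_bn_init <- function(name, c) bn_spec(name, c)

make_bottleneck_block <- function(prefix, c_in, width, stride, expansion,
                                  need_downsample, init = TRUE) {
  c_out <- width * expansion
  conv1 <- conv_spec(paste0(prefix, ".conv1"), c_in, width, 1L,
                     stride = 1L, padding = 0L, init = init)
  conv2 <- conv_spec(paste0(prefix, ".conv2"), width, width, 3L,
                     stride = stride, padding = 1L, init = init)
  conv3 <- conv_spec(paste0(prefix, ".conv3"), width, c_out, 1L,
                     stride = 1L, padding = 0L, init = init)
  ds <- NULL
  if (need_downsample) {
    ds <- list(
      conv = conv_spec(paste0(prefix, ".downsample.conv"), c_in, c_out, 1L,
                       stride = stride, padding = 0L, init = init),
      bn = make_bn_init(paste0(prefix, ".downsample.bn"), c_out))
  }
  bottleneck_spec(prefix,
                  conv1, make_bn_init(paste0(prefix, ".bn1"), width),
                  conv2, make_bn_init(paste0(prefix, ".bn2"), width),
                  conv3, make_bn_init(paste0(prefix, ".bn3"), c_out),
                  downsample = ds)
}

build_bottleneck_graph <- function(name, num_classes, widths,
                                   blocks_per_stage, input_shape,
                                   stem_kernel, stem_stride, stem_pool,
                                   seed = NULL, init = TRUE) {
  if (length(input_shape) != 3L || any(input_shape <= 0))
    stop("input_shape must be three positive integers (channels, height, width)",
         call. = FALSE)
  if (num_classes < 2L)
    stop("num_classes must be >= 2", call. = FALSE)
  if (length(widths) != length(blocks_per_stage) ||
      any(widths < 1L) || any(blocks_per_stage < 1L))
    stop("widths and blocks_per_stage must be equal-length vectors of positive integers",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  expansion <- 4L
  stem_conv <- conv_spec("stem.conv", input_shape[1], widths[1], stem_kernel,
                         stride = stem_stride,
                         padding = (stem_kernel - 1L) %/% 2L, init = init)
  stem <- list(conv = stem_conv, bn = make_bn_init("stem.bn", widths[1]))
  blocks <- list()
  c_in <- widths[1]
  for (s in seq_along(widths)) {
    for (b in seq_len(blocks_per_stage[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      need_ds <- b == 1L   # width change (expansion) or stride change
      blk <- make_bottleneck_block(sprintf("s%d.b%d", s, b), c_in, widths[s],
                                   stride, expansion, need_ds, init = init)
      blocks[[length(blocks) + 1L]] <- blk
      c_in <- widths[s] * expansion
    }
  }
  head <- make_head(c_in, num_classes, init = init)
  g <- model_graph("bottleneck", stem = stem, stem_pool = stem_pool,
                   blocks = blocks, head = head, input_shape = input_shape,
                   metadata = list(name = name, seed = seed))
  validate_graph(g)
}

#' Build a ResNet50 classifier graph
#'
#' The standard bottleneck ResNet50: a 7x7/stride-2 stem convolution with 64
#' output channels followed by a 3x3/stride-2 max pool, four stages of
#' 3/4/6/3 bottleneck blocks with mid-widths 64/128/256/512 (expansion 4,
#' stride on the middle 3x3 convolution of each stage's first block), global
#' average pooling and a linear head. Convolutions are bias-free; every
#' convolution is followed by batch normalization.
#'
#' @param num_classes number of output classes (>= 2); the default 2 is the
#'   normal-versus-pneumonia setting.
#' @param input_shape `c(channels, height, width)`; parameter and FLOP
#'   figures are calibrated at `c(3, 224, 224)`.
#' @param seed optional integer seed for the He-uniform weight
#'   initialization.
#' @param init if `FALSE`, build a shape-only graph without weight arrays
#'   (sufficient for accounting).
#' @return a `model_graph`.
#' @examples
#' g <- build_resnet50(num_classes = 2, seed = 1, init = FALSE)
#' n_params(g)   # 23512130
#' @export
build_resnet50 <- function(num_classes = 2L, input_shape = c(3L, 224L, 224L),
                           seed = NULL, init = TRUE) {
  build_bottleneck_graph("resnet50", num_classes,
                         widths = c(64L, 128L, 256L, 512L),
                         blocks_per_stage = c(3L, 4L, 6L, 3L),
                         input_shape = input_shape,
                         stem_kernel = 7L, stem_stride = 2L, stem_pool = TRUE,
                         seed = seed, init = init)
}

#' Build a miniature bottleneck network
#'
#' A desk-scale test double with exactly the topology of ResNet50 -- stages
#' of three-convolution bottleneck blocks with expansion 4, projection
#' shortcuts on each stage's first block -- but tiny widths and a 3x3
#' stride-1 stem without max pooling, so that every pruning and ghost
#' operation (and training itself) runs in milliseconds.
#'
#' @param num_classes number of output classes (>= 2).
#' @param widths per-stage bottleneck mid-widths.
#' @param blocks_per_stage number of blocks in each stage (same length as
#'   `widths`).
#' @param input_shape `c(channels, height, width)`.
#' @param seed optional integer seed for weight initialization.
#' @param init if `FALSE`, build without weight arrays.
#' @return a `model_graph`.
#' @examples
#' g <- build_tiny_resnet(2, widths = c(8, 16), blocks_per_stage = c(1, 1),
#'                        input_shape = c(3, 32, 32), seed = 1)
#' @export
build_tiny_resnet <- function(num_classes = 2L, widths = c(8L, 16L),
                              blocks_per_stage = c(1L, 1L),
                              input_shape = c(3L, 32L, 32L),
                              seed = NULL, init = TRUE) {
  build_bottleneck_graph("tiny_resnet", num_classes,
                         widths = as.integer(widths),
                         blocks_per_stage = as.integer(blocks_per_stage),
                         input_shape = input_shape,
                         stem_kernel = 3L, stem_stride = 1L, stem_pool = FALSE,
                         seed = seed, init = init)
}
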