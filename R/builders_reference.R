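# Reference lightweight architectures (MobileNetV2 and ShuffleNetV2 x0.5),
# built as "flat" graphs: ordered layer rows with precomputed output spatial
# sizes. They exist to calibrate the accounting module against two
# well-known parameter budgets and are never trained or pruned here.

flat_builder <- function(input_hw) {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$h <- input_hw[1]; env$w <- input_hw[2]
  env$i <- 0L
  env
}

fb_add <- function(env, row) {
  env$rows[[length(env$rows) + 1L]] <- row
  invisible(env)
}

# conv + bn (+ optional activation), updating tracked spatial size
fb_conv_bn <- function(env, name, c_in, c_out, k, stride = 1L, groups = 1L,
                       act = TRUE, init = TRUE) {
  pad <- (k - 1L) %/% 2L
  env$h <- (env$h + 2L * pad - k) %/% stride + 1L
  env$w <- (env$w + 2L * pad - k) %/% stride + 1L
  cv <- conv_spec(name, c_in, c_out, k, stride = stride, padding = pad,
                  groups = groups, init = init)
  fb_add(env, list(kind = "conv", name = name, spec = cv,
                   h = env$h, w = env$w))
  fb_add(env, list(kind = "bn", name = paste0(name, ".bn"),
                   spec = bn_spec(paste0(name, ".bn"), c_out),
                   h = env$h, w = env$w))
  if (act)
    fb_add(env, list(kind = "act", name = paste0(name, ".act"),
                     c = c_out, h = env$h, w = env$w))
  invisible(env)
}

fb_pool <- function(env, name, c, k = 3L, stride = 2L) {
  pad <- (k - 1L) %/% 2L
  env$h <- (env$h + 2L * pad - k) %/% stride + 1L
  env$w <- (env$w + 2L * pad - k) %/% stride + 1L
  fb_add(env, list(kind = "pool", name = name, c = c, h = env$h, w = env$w))
}

fb_eltwise <- function(env, name, c) {
  fb_add(env, list(kind = "add", name = name, c = c, h = env$h, w = env$w))
}

build_mobilenet_v2 <- function(num_classes, input_shape, init = TRUE) {
  env <- flat_builder(input_shape[2:3])
  fb_conv_bn(env, "conv1", input_shape[1], 32L, 3L, stride = 2L, init = init)
  # (expansion t, out channels c, repeats n, first stride s)
  cfg <- list(c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2), c(6, 64, 4, 2),
              c(6, 96, 3, 1), c(6, 160, 3, 2), c(6, 320, 1, 1))
  c_in <- 32L
  bi <- 0L
  for (row in cfg) {
    t <- row[1]; c_out <- as.integer(row[2]); n <- row[3]; s0 <- row[4]
    for (j in seq_len(n)) {
      bi <- bi + 1L
      stride <- if (j == 1L) as.integer(s0) else 1L
      hidden <- as.integer(t * c_in)
      pre <- sprintf("ir%d", bi)
      if (t != 1)
        fb_conv_bn(env, paste0(pre, ".expand"), c_in, hidden, 1L, init = init)
      fb_conv_bn(env, paste0(pre, ".dw"), hidden, hidden, 3L, stride = stride,
                 groups = hidden, init = init)
      fb_conv_bn(env, paste0(pre, ".project"), hidden, c_out, 1L, act = FALSE,
                 init = init)
      if (stride == 1L && c_in == c_out)
        fb_eltwise(env, paste0(pre, ".add"), c_out)
      c_in <- c_out
    }
  }
  fb_conv_bn(env, "conv_last", c_in, 1280L, 1L, init = init)
  model_graph("flat", layers = env$rows,
              head = make_head(1280L, num_classes, init = init),
              input_shape = input_shape, final_hw = c(env$h, env$w),
              metadata = list(name = "mobilenet_v2"))
}

shuffle_unit_down <- function(env, pre, c_in, c_out, init) {
  b <- c_out %/% 2L
  h0 <- env$h; w0 <- env$w
  # branch 1: depthwise stride 2 on the full input, then pointwise
  fb_conv_bn(env, paste0(pre, ".b1.dw"), c_in, c_in, 3L, stride = 2L,
             groups = c_in, act = FALSE, init = init)
  fb_conv_bn(env, paste0(pre, ".b1.pw"), c_in, b, 1L, init = init)
  # branch 2 shares the unit input; reset tracked size before emitting it
  env$h <- h0; env$w <- w0
  fb_conv_bn(env, paste0(pre, ".b2.pw1"), c_in, b, 1L, init = init)
  fb_conv_bn(env, paste0(pre, ".b2.dw"), b, b, 3L, stride = 2L, groups = b,
             act = FALSE, init = init)
  fb_conv_bn(env, paste0(pre, ".b2.pw2"), b, b, 1L, init = init)
}

shuffle_unit_basic <- function(env, pre, c, init) {
  b <- c %/% 2L   # only the second half of the split is transformed
  fb_conv_bn(env, paste0(pre, ".pw1"), b, b, 1L, init = init)
  fb_conv_bn(env, paste0(pre, ".dw"), b, b, 3L, groups = b, act = FALSE,
             init = init)
  fb_conv_bn(env, paste0(pre, ".pw2"), b, b, 1L, init = init)
}

build_shufflenet_v2_x0_5 <- function(num_classes, input_shape, init = TRUE) {
  env <- flat_builder(input_shape[2:3])
  fb_conv_bn(env, "conv1", input_shape[1], 24L, 3L, stride = 2L, init = init)
  fb_pool(env, "maxpool", 24L)
  stage_out <- c(48L, 96L, 192L)
  repeats <- c(4L, 8L, 4L)
  c_in <- 24L
  for (s in seq_along(stage_out)) {
    c_out <- stage_out[s]
    for (j in seq_len(repeats[s])) {
      pre <- sprintf("st%d.u%d", s + 1L, j)
      if (j == 1L) shuffle_unit_down(env, pre, c_in, c_out, init)
      else shuffle_unit_basic(env, pre, c_out, init)
      c_in <- c_out
    }
  }
  fb_conv_bn(env, "conv5", c_in, 1024L, 1L, init = init)
  model_graph("flat", layers = env$rows,
              head = make_head(1024L, num_classes, init = init),
              input_shape = input_shape, final_hw = c(env$h, env$w),
              metadata = list(name = "shufflenet_v2_x0_5"))
}

#' Build a reference lightweight architecture
#'
#' Standard MobileNetV2 (width 1.0) or ShuffleNetV2 at 0.5x width, with the
#' classifier head resized to `num_classes`. These graphs carry full layer
#' shape information (and weights, if `init = TRUE`) but support only the
#' accounting module -- they are the calibration baselines a compressed
#' ResNet50 is compared against, not trainable models here.
#'
#' @param arch_name `"mobilenet_v2"` or `"shufflenet_v2_x0_5"`.
#' @param num_classes number of output classes.
#' @param input_shape `c(channels, height, width)`.
#' @param seed optional seed for weight initialization.
#' @param init if `FALSE`, build without weight arrays.
#' @return a `model_graph` of family `"flat"`.
#' @examples
#' n_params(build_reference("mobilenet_v2", 2, init = FALSE))  # 2226434
#' @export
build_reference <- function(arch_name, num_classes = 2L,
                            input_shape = c(3L, 224L, 224L), seed = NULL,
                            init = TRUE) {
  if (num_classes < 2L) stop("num_classes must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- switch(arch_name,
    mobilenet_v2 = build_mobilenet_v2(num_classes, as.integer(input_shape),
                                      init = init),
    shufflenet_v2_x0_5 = build_shufflenet_v2_x0_5(num_classes,
                                                  as.integer(input_shape),
                                                  init = init),
    stop("unknown arch_name '", arch_name,
         "'; valid names: mobilenet_v2, shufflenet_v2_x0_5", call. = FALSE))
  g$metadata$seed <- seed
  validate_graph(g)
}
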