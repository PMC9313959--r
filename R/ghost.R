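# Ghost decomposition: replace a dense convolution producing n feature maps
# by a primary convolution producing the m = ceil(n/s) intrinsic maps plus
# cheap depthwise linear operations generating the remaining n - m maps from
# them. Applied after pruning: pruning first leaves fewer channels for the
# primary convolution to produce, which is what makes the combined
# compression stronger than the reverse order.

#' Ghost decomposition configuration
#'
#' @param s integer ratio >= 2: a fraction `1/s` of each targeted layer's
#'   output channels is produced by the primary (dense) convolution, the
#'   rest by cheap depthwise operations. `s = 2` (half intrinsic, half
#'   cheap) is the calibrated default.
#' @param d odd spatial size of the cheap depthwise kernel.
#' @param target_layers character vector of convolution names to decompose,
#'   or `NULL` for the default set: every bottleneck convolution (conv1,
#'   conv2, conv3), excluding the stem, downsample projections and the head.
#' @return an object of class `ghost_config`.
#' @export
ghost_config <- function(s = 2L, d = 3L, target_layers = NULL) {
  s <- as.integer(s); d <- as.integer(d)
  if (s < 2L) stop("ghost ratio s must be an integer >= 2", call. = FALSE)
  if (d < 1L || d %% 2L == 0L)
    stop("cheap kernel size d must be odd and >= 1", call. = FALSE)
  structure(list(s = s, d = d, target_layers = target_layers),
            class = "ghost_config")
}

#' Decompose one convolution into a ghost module
#'
#' The primary convolution keeps the original kernel size, stride and
#' padding but produces only `m = ceiling(c_out / s)` output channels; the
#' cheap part is a bias-free depthwise `d x d`, stride-1 convolution that
#' maps intrinsic maps to the remaining `c_out - m` maps, so the
#' concatenated output has exactly the replaced convolution's shape. Both
#' parts are bias-free (batch normalization follows the module). The
#' primary weights are the first `m` filters of the original convolution;
#' cheap kernels are He-uniform initialized from the current RNG stream.
#'
#' @param conv a dense [conv_spec()] with `c_out >= 2` and `groups == 1`.
#' @param cfg a [ghost_config()].
#' @return an object of class `ghost_conv` with fields `primary`, `cheap`,
#'   `n` (total output channels), `s`, `d`.
#' @examples
#' cv <- conv_spec("c", 16, 64, 3, padding = 1, init = FALSE)
#' g <- ghostify_conv(cv, ghost_config(s = 2, d = 3))
#' n_params(g)  # 4896, versus 9216 dense
#' @export
ghostify_conv <- function(conv, cfg) {
  stopifnot(inherits(conv, "conv_spec"), inherits(cfg, "ghost_config"))
  n <- conv$c_out
  if (conv$groups != 1L)
    stop("conv '", conv$name,
         "': ghost decomposition of grouped/depthwise convolutions is degenerate",
         call. = FALSE)
  if (n < 2L)
    stop("conv '", conv$name,
         "': a 1-channel convolution cannot be decomposed", call. = FALSE)
  m <- as.integer(ceiling(n / cfg$s))
  q <- n - m
  if (q < 1L)
    stop("conv '", conv$name, "': ratio s = ", cfg$s,
         " leaves no cheap maps for c_out = ", n, call. = FALSE)
  # Each cheap map is generated from one intrinsic map. When q is a
  # multiple of m every intrinsic map feeds q/m cheap maps; otherwise
  # (s = 2 with odd width) the first q intrinsic maps feed one each.
  if (q %% m == 0L) {
    cheap_cin <- m
    cheap_groups <- m
  } else if (q < m) {
    cheap_cin <- q
    cheap_groups <- q
  } else {
    stop("conv '", conv$name, "': c_out = ", n,
         " is not divisible by s = ", cfg$s,
         " in a way the cheap operation supports", call. = FALSE)
  }
  has_w <- !is.null(conv$weights)
  primary <- conv_spec(paste0(conv$name, ".primary"), conv$c_in, m,
                       conv$k_h, conv$k_w, conv$stride, conv$padding,
                       groups = 1L, has_bias = FALSE,
                       weights = if (has_w)
                         conv$weights[seq_len(m), , , , drop = FALSE],
                       init = FALSE)
  cheap <- conv_spec(paste0(conv$name, ".cheap"), cheap_cin, q,
                     cfg$d, cfg$d, stride = 1L,
                     padding = (cfg$d - 1L) %/% 2L,
                     groups = cheap_groups, has_bias = FALSE,
                     init = has_w)
  out <- structure(list(name = conv$name, primary = primary, cheap = cheap,
                        n = n, s = cfg$s, d = cfg$d),
                   class = "ghost_conv")
  # the decomposition provably shrinks the layer whenever the dense kernel
  # outweighs a cheap kernel; check that guarantee per layer
  if (conv$k_h * conv$k_w * conv$c_in > cfg$d^2)
    stopifnot(n_params(out) < n_params(conv))
  out
}

default_ghost_targets <- function(graph) {
  unlist(lapply(graph$blocks,
                function(b) paste0(b$name, c(".conv1", ".conv2", ".conv3"))))
}

#' Apply ghost decomposition across a graph
#'
#' Replaces each targeted convolution by its ghost module; batch-norm and
#' activation placement after each module is unchanged (the module's
#' concatenated output has the same width the dense convolution had). All
#' non-targeted layers are untouched.
#'
#' @param graph a bottleneck-family `model_graph`.
#' @param cfg a [ghost_config()]; a `NULL` `target_layers` means the default
#'   all-bottleneck-convolution set. An empty character vector leaves the
#'   graph unchanged.
#' @return the decomposed `model_graph`.
#' @export
ghostify_model <- function(graph, cfg) {
  stopifnot(inherits(cfg, "ghost_config"))
  if (graph$family != "bottleneck")
    stop("ghost decomposition is only defined for bottleneck-family graphs",
         call. = FALSE)
  targets <- cfg$target_layers %||% default_ghost_targets(graph)
  if (length(targets) == 0L) return(graph)
  known <- unlist(lapply(graph$blocks, function(b)
    paste0(b$name, c(".conv1", ".conv2", ".conv3"))))
  bad <- setdiff(targets, known)
  if (length(bad))
    stop("target layer(s) not found among bottleneck convolutions: ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (i in seq_along(graph$blocks)) {
    blk <- graph$blocks[[i]]
    for (slot in c("conv1", "conv2", "conv3")) {
      nm <- paste0(blk$name, ".", slot)
      if (nm %in% targets) {
        if (inherits(blk[[slot]], "ghost_conv"))
          stop("layer '", nm, "' is already a ghost module", call. = FALSE)
        blk[[slot]] <- ghostify_conv(blk[[slot]], cfg)
      }
    }
    graph$blocks[[i]] <- blk
    validate_bottleneck(blk)
  }
  graph$metadata$transforms <- c(graph$metadata$transforms,
                                 sprintf("ghost(s=%d,d=%d)", cfg$s, cfg$d))
  validate_graph(graph)
}

#' Prune, then ghost-decompose, a graph
#'
#' The full compression pipeline in the order that compresses hardest:
#' channel pruning first (so the primary convolutions of the subsequent
#' ghost decomposition act on the already-thinned layers), then ghost
#' decomposition. Running the stages in the reverse order would leave
#' every pruned layer with more surviving channels at equal rates, and
#' hence a larger model. Both transforms are recorded in
#' `metadata$transforms`.
#'
#' @param graph a bottleneck-family `model_graph`.
#' @param plan a `prune_plan` (see [make_plan()]).
#' @param cfg a [ghost_config()].
#' @return the compressed `model_graph`.
#' @export
compress_model <- function(graph, plan, cfg) {
  ghostify_model(apply_prune(graph, plan), cfg)
}
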