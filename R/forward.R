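# Forward and backward passes over bottleneck model graphs, plus the
# parameter-tree utilities the SGD loop uses. Only the "bottleneck" family
# supports execution; the flat reference graphs exist for accounting alone.

layer_fwd <- function(spec, x, keep = FALSE) {
  if (inherits(spec, "ghost_conv")) layer_fwd_ghost(spec, x, keep)
  else conv2d_fwd(x, spec$weights, if (spec$has_bias) spec$bias else NULL,
                  spec$stride, spec$padding, spec$groups, keep)
}

layer_fwd_ghost <- function(spec, x, keep = FALSE) {
  f1 <- layer_fwd(spec$primary, x, keep)
  m <- spec$primary$c_out
  q <- spec$n - m
  cin <- spec$cheap$c_in
  xin <- f1$y[, , seq_len(cin), , drop = FALSE]
  f2 <- conv2d_fwd(xin, spec$cheap$weights, NULL, spec$cheap$stride,
                   spec$cheap$padding, spec$cheap$groups, keep)
  d <- dim(f1$y)
  y <- array(0, c(d[1], d[2], spec$n, d[4]))
  y[, , seq_len(m), ] <- f1$y
  y[, , m + seq_len(q), ] <- f2$y
  cache <- if (keep)
    list(primary = f1$cache, cheap = f2$cache, m = m, q = q, cin = cin)
  list(y = y, cache = cache)
}

layer_bwd <- function(spec, dy, cache) {
  if (inherits(spec, "ghost_conv")) return(layer_bwd_ghost(spec, dy, cache))
  b <- conv2d_bwd(dy, cache)
  g <- list(w = b$dw)
  if (spec$has_bias) g$b <- b$db
  list(dx = b$dx, grad = g)
}

layer_bwd_ghost <- function(spec, dy, cache) {
  m <- cache$m; q <- cache$q
  dy1 <- dy[, , seq_len(m), , drop = FALSE]
  dy2 <- dy[, , m + seq_len(q), , drop = FALSE]
  b2 <- conv2d_bwd(dy2, cache$cheap)
  dy1[, , seq_len(cache$cin), ] <-
    dy1[, , seq_len(cache$cin), ] + b2$dx
  b1 <- conv2d_bwd(dy1, cache$primary)
  list(dx = b1$dx,
       grad = list(primary = list(w = b1$dw), cheap = list(w = b2$dw)))
}

bottleneck_fwd <- function(blk, x, train = FALSE, keep = FALSE) {
  cc <- list()
  f1 <- layer_fwd(blk$conv1, x, keep); cc$conv1 <- f1$cache
  b1 <- bn_fwd(f1$y, blk$bn1, train, keep); blk$bn1 <- b1$bn; cc$bn1 <- b1$cache
  r1 <- relu_fwd(b1$y, keep); cc$relu1 <- r1$cache
  f2 <- layer_fwd(blk$conv2, r1$y, keep); cc$conv2 <- f2$cache
  b2 <- bn_fwd(f2$y, blk$bn2, train, keep); blk$bn2 <- b2$bn; cc$bn2 <- b2$cache
  r2 <- relu_fwd(b2$y, keep); cc$relu2 <- r2$cache
  f3 <- layer_fwd(blk$conv3, r2$y, keep); cc$conv3 <- f3$cache
  b3 <- bn_fwd(f3$y, blk$bn3, train, keep); blk$bn3 <- b3$bn; cc$bn3 <- b3$cache
  if (!is.null(blk$downsample)) {
    fd <- layer_fwd(blk$downsample$conv, x, keep); cc$ds_conv <- fd$cache
    bd <- bn_fwd(fd$y, blk$downsample$bn, train, keep)
    blk$downsample$bn <- bd$bn; cc$ds_bn <- bd$cache
    short <- bd$y
  } else {
    short <- x
  }
  s <- b3$y + short
  ro <- relu_fwd(s, keep); cc$relu_out <- ro$cache
  list(y = ro$y, cache = cc, block = blk)
}

bottleneck_bwd <- function(blk, cache, dy) {
  dsum <- relu_bwd(dy, cache$relu_out)
  g <- list()
  bb3 <- bn_bwd(dsum, cache$bn3)
  lb3 <- layer_bwd(blk$conv3, bb3$dx, cache$conv3)
  dr2 <- relu_bwd(lb3$dx, cache$relu2)
  bb2 <- bn_bwd(dr2, cache$bn2)
  lb2 <- layer_bwd(blk$conv2, bb2$dx, cache$conv2)
  dr1 <- relu_bwd(lb2$dx, cache$relu1)
  bb1 <- bn_bwd(dr1, cache$bn1)
  lb1 <- layer_bwd(blk$conv1, bb1$dx, cache$conv1)
  g$conv1 <- lb1$grad
  g$bn1 <- list(scale = bb1$dscale, shift = bb1$dshift)
  g$conv2 <- lb2$grad
  g$bn2 <- list(scale = bb2$dscale, shift = bb2$dshift)
  g$conv3 <- lb3$grad
  g$bn3 <- list(scale = bb3$dscale, shift = bb3$dshift)
  if (!is.null(blk$downsample)) {
    bbd <- bn_bwd(dsum, cache$ds_bn)
    lbd <- layer_bwd(blk$downsample$conv, bbd$dx, cache$ds_conv)
    g$downsample <- list(conv = lbd$grad,
                         bn = list(scale = bbd$dscale, shift = bbd$dshift))
    dx <- lb1$dx + lbd$dx
  } else {
    dx <- lb1$dx + dsum
  }
  list(dx = dx, grad = g)
}

graph_fwd <- function(graph, x, train = FALSE, keep = train) {
  if (graph$family != "bottleneck")
    stop("forward pass is only implemented for bottleneck-family graphs",
         call. = FALSE)
  cc <- list(blocks = vector("list", length(graph$blocks)))
  fs <- layer_fwd(graph$stem$conv, x, keep); cc$stem_conv <- fs$cache
  bs <- bn_fwd(fs$y, graph$stem$bn, train, keep)
  graph$stem$bn <- bs$bn; cc$stem_bn <- bs$cache
  rs <- relu_fwd(bs$y, keep); cc$stem_relu <- rs$cache
  h <- rs$y
  if (graph$stem_pool) {
    mp <- maxpool_fwd(h, keep = keep); cc$stem_pool <- mp$cache
    h <- mp$y
  }
  for (i in seq_along(graph$blocks)) {
    bf <- bottleneck_fwd(graph$blocks[[i]], h, train, keep)
    graph$blocks[[i]] <- bf$block
    cc$blocks[[i]] <- bf$cache
    h <- bf$y
  }
  gp <- gap_fwd(h, keep); cc$gap <- gp$cache
  lf <- linear_fwd(gp$y, graph$head$W, graph$head$b, keep)
  cc$head <- lf$cache
  list(logits = lf$y, cache = cc, graph = graph)
}

graph_bwd <- function(graph, cache, dlogits) {
  lb <- linear_bwd(dlogits, cache$head, graph$head$W)
  g <- list()
  dh <- gap_bwd(lb$dx, cache$gap)
  gblocks <- vector("list", length(graph$blocks))
  for (i in rev(seq_along(graph$blocks))) {
    bb <- bottleneck_bwd(graph$blocks[[i]], cache$blocks[[i]], dh)
    gblocks[[i]] <- bb$grad
    dh <- bb$dx
  }
  if (graph$stem_pool) dh <- maxpool_bwd(dh, cache$stem_pool)
  dr <- relu_bwd(dh, cache$stem_relu)
  bb <- bn_bwd(dr, cache$stem_bn)
  lbs <- layer_bwd(graph$stem$conv, bb$dx, cache$stem_conv)
  g$stem <- list(conv = lbs$grad,
                 bn = list(scale = bb$dscale, shift = bb$dshift))
  g$blocks <- gblocks
  g$head <- list(W = lb$dW, b = lb$db)
  g
}

#' Run a forward pass
#'
#' Computes class logits for a batch of images with the graph in evaluation
#' mode (running batch-norm statistics). Deterministic: two calls with
#' identical weights and input return identical output.
#'
#' @param graph a bottleneck-family `model_graph` with weights.
#' @param x input array `(H, W, C, N)` or a single image `(H, W, C)`.
#' @return a `num_classes x N` matrix of logits.
#' @export
graph_forward <- function(graph, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  graph_fwd(graph, x, train = FALSE, keep = FALSE)$logits
}

# ---- parameter trees ------------------------------------------------------
# Nested lists of numeric arrays congruent with the gradient trees produced
# by graph_bwd; used by the SGD update and by lr-zero invariance tests.

spec_params <- function(spec) {
  if (inherits(spec, "ghost_conv"))
    return(list(primary = list(w = spec$primary$weights),
                cheap = list(w = spec$cheap$weights)))
  p <- list(w = spec$weights)
  if (spec$has_bias) p$b <- spec$bias
  p
}

spec_set_params <- function(spec, p) {
  if (inherits(spec, "ghost_conv")) {
    spec$primary$weights <- p$primary$w
    spec$cheap$weights <- p$cheap$w
    return(spec)
  }
  spec$weights <- p$w
  if (spec$has_bias) spec$bias <- p$b
  spec
}

params_tree <- function(graph) {
  blk_params <- function(blk) {
    g <- list(conv1 = spec_params(blk$conv1),
              bn1 = list(scale = blk$bn1$scale, shift = blk$bn1$shift),
              conv2 = spec_params(blk$conv2),
              bn2 = list(scale = blk$bn2$scale, shift = blk$bn2$shift),
              conv3 = spec_params(blk$conv3),
              bn3 = list(scale = blk$bn3$scale, shift = blk$bn3$shift))
    if (!is.null(blk$downsample))
      g$downsample <- list(conv = spec_params(blk$downsample$conv),
                           bn = list(scale = blk$downsample$bn$scale,
                                     shift = blk$downsample$bn$shift))
    g
  }
  list(stem = list(conv = spec_params(graph$stem$conv),
                   bn = list(scale = graph$stem$bn$scale,
                             shift = graph$stem$bn$shift)),
       blocks = lapply(graph$blocks, blk_params),
       head = list(W = graph$head$W, b = graph$head$b))
}

graph_set_params <- function(graph, pt) {
  graph$stem$conv <- spec_set_params(graph$stem$conv, pt$stem$conv)
  graph$stem$bn$scale <- pt$stem$bn$scale
  graph$stem$bn$shift <- pt$stem$bn$shift
  for (i in seq_along(graph$blocks)) {
    blk <- graph$blocks[[i]]; p <- pt$blocks[[i]]
    blk$conv1 <- spec_set_params(blk$conv1, p$conv1)
    blk$bn1$scale <- p$bn1$scale; blk$bn1$shift <- p$bn1$shift
    blk$conv2 <- spec_set_params(blk$conv2, p$conv2)
    blk$bn2$scale <- p$bn2$scale; blk$bn2$shift <- p$bn2$shift
    blk$conv3 <- spec_set_params(blk$conv3, p$conv3)
    blk$bn3$scale <- p$bn3$scale; blk$bn3$shift <- p$bn3$shift
    if (!is.null(blk$downsample)) {
      blk$downsample$conv <- spec_set_params(blk$downsample$conv,
                                             p$downsample$conv)
      blk$downsample$bn$scale <- p$downsample$bn$scale
      blk$downsample$bn$shift <- p$downsample$bn$shift
    }
    graph$blocks[[i]] <- blk
  }
  graph$head$W <- pt$head$W
  graph$head$b <- pt$head$b
  graph
}

# Elementwise map over one or two congruent parameter trees.
tree_map <- function(f, a) {
  if (!is.list(a)) return(f(a))
  out <- vector("list", length(a))
  names(out) <- names(a)
  for (i in seq_along(a)) out[[i]] <- tree_map(f, a[[i]])
  out
}

tree_map2 <- function(f, a, b) {
  if (!is.list(a)) return(f(a, b))
  out <- vector("list", length(a))
  names(out) <- names(a)
  for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
  out
}

#' All batch-norm scale factors of a graph
#'
#' Concatenates the per-channel batch-norm scale vectors of every
#' normalization layer, in graph order. This is the vector the L1 sparsity
#' penalty acts on when emulating sparsity-trained slimming baselines.
#'
#' @param graph a bottleneck-family `model_graph`.
#' @return a numeric vector.
#' @export
all_bn_scales <- function(graph) {
  out <- list(graph$stem$bn$scale)
  for (blk in graph$blocks) {
    out <- c(out, list(blk$bn1$scale, blk$bn2$scale, blk$bn3$scale))
    if (!is.null(blk$downsample)) out <- c(out, list(blk$downsample$bn$scale))
  }
  unlist(out)
}
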