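# Controllable per-layer channel pruning. Channels are scored by the
# magnitude of their batch-norm scale factor; each prunable layer keeps its
# k largest-magnitude channels, where k is set per layer by the pruning
# rate. Only conv1 and conv2 of each bottleneck are prunable: conv3, the
# downsample projection and the stem set the widths the shortcut additions
# depend on, and removing channels there would break the residual dimension
# matching.

#' Rank channels by batch-norm scale magnitude
#'
#' Orders a normalization layer's channels by ascending `|scale|`, the
#' channel-importance score: the channels listed first are the first to be
#' pruned. The ordering is total; ties are broken by ascending channel
#' index.
#'
#' @param bn a [bn_spec()].
#' @return an integer permutation of `1:bn$c` (1-based channel indices).
#' @examples
#' rank_channels(bn_spec("b", 3, scale = c(0.5, 0.1, 0.9)))  # 2 1 3
#' @export
rank_channels <- function(bn) {
  stopifnot(inherits(bn, "bn_spec"))
  order(abs(bn$scale), seq_len(bn$c))
}

# Survivor count for a layer of width c_out pruned at rate lambda.
# round() is the calibrated rule (floor() of the pruned count is the
# documented fallback); at least one channel always survives, so no layer
# can vanish at any rate < 1.
kept_count <- function(c_out, lambda, rounding = c("round", "floor")) {
  rounding <- match.arg(rounding)
  pruned <- switch(rounding,
                   round = round(c_out * lambda),
                   floor = floor(c_out * lambda))
  max(1L, as.integer(c_out - pruned))
}

prunable_layers <- function(graph) {
  if (graph$family != "bottleneck")
    stop("pruning is only defined for bottleneck-family graphs", call. = FALSE)
  unlist(lapply(graph$blocks,
                function(b) paste0(b$name, c(".conv1", ".conv2"))))
}

#' Build a pruning plan
#'
#' Resolves per-layer pruning rates into kept-channel index sets. For a
#' prunable layer with `c_out` channels and rate `lambda`, the kept count is
#' `max(1, c_out - round(c_out * lambda))` and the kept set is the `k`
#' channels with the largest batch-norm scale magnitude (ties resolved
#' toward higher channel indices, consistently with [rank_channels()]).
#'
#' @param graph a bottleneck-family `model_graph`.
#' @param rates a single rate in `[0, 1)` applied to every prunable layer,
#'   or a named numeric vector/list of rates keyed by prunable layer name
#'   (`"<block>.conv1"` / `"<block>.conv2"`). Layers not named keep rate 0.
#' @param rounding survivor rounding rule; `"round"` is the calibrated
#'   default.
#' @return an object of class `prune_plan`: a list with `entries` (one per
#'   prunable layer: `layer`, `rate`, `kept` 1-based sorted indices) and
#'   `rounding`.
#' @export
make_plan <- function(graph, rates, rounding = c("round", "floor")) {
  rounding <- match.arg(rounding)
  prunable <- prunable_layers(graph)
  if (is.list(rates)) rates <- unlist(rates)
  if (is.null(names(rates))) {
    if (length(rates) != 1L)
      stop("unnamed 'rates' must be a single global rate", call. = FALSE)
    rates <- stats::setNames(rep(rates, length(prunable)), prunable)
  } else {
    bad <- setdiff(names(rates), prunable)
    if (length(bad))
      stop("layer(s) ", paste(bad, collapse = ", "), " are not prunable: ",
           "only conv1 and conv2 of each bottleneck may be pruned, because ",
           "conv3, downsample and stem widths are fixed by the shortcut ",
           "dimension-matching constraint", call. = FALSE)
    full <- stats::setNames(rep(0, length(prunable)), prunable)
    full[names(rates)] <- unlist(rates)
    rates <- full
  }
  if (any(rates < 0 | rates >= 1))
    stop("pruning rates must lie in [0, 1)", call. = FALSE)
  bns <- list()
  for (blk in graph$blocks) {
    bns[[paste0(blk$name, ".conv1")]] <- blk$bn1
    bns[[paste0(blk$name, ".conv2")]] <- blk$bn2
  }
  entries <- lapply(prunable, function(nm) {
    bn <- bns[[nm]]
    k <- kept_count(bn$c, rates[[nm]], rounding)
    ord <- rank_channels(bn)
    kept <- sort(ord[(bn$c - k + 1L):bn$c])
    list(layer = nm, rate = as.numeric(rates[[nm]]), kept = kept)
  })
  names(entries) <- prunable
  structure(list(entries = entries, rounding = rounding),
            class = "prune_plan")
}

#' @export
print.prune_plan <- function(x, ...) {
  cat("<prune_plan> ", length(x$entries), " prunable layers (rounding: ",
      x$rounding, ")\n", sep = "")
  for (e in x$entries)
    cat(sprintf("  %-16s rate %.2f  kept %d\n", e$layer, e$rate,
                length(e$kept)))
  invisible(x)
}

subset_bn <- function(bn, kept) {
  bn_spec(bn$name, length(kept), scale = bn$scale[kept],
          shift = bn$shift[kept], mean = bn$mean[kept], sd = bn$sd[kept],
          eps = bn$eps)
}

# Keep only output channels `kept` of a dense convolution.
subset_conv_out <- function(cv, kept) {
  conv_spec(cv$name, cv$c_in, length(kept), cv$k_h, cv$k_w, cv$stride,
            cv$padding, cv$groups, cv$has_bias,
            weights = if (!is.null(cv$weights))
              cv$weights[kept, , , , drop = FALSE],
            bias = if (cv$has_bias) cv$bias[kept], init = FALSE)
}

# Keep only input channels `kept` of a dense convolution.
subset_conv_in <- function(cv, kept) {
  conv_spec(cv$name, length(kept), cv$c_out, cv$k_h, cv$k_w, cv$stride,
            cv$padding, cv$groups, cv$has_bias,
            weights = if (!is.null(cv$weights))
              cv$weights[, kept, , , drop = FALSE],
            bias = cv$bias, init = FALSE)
}

#' Apply a pruning plan to a graph
#'
#' Performs the channel surgery described by a [make_plan()] result and
#' returns a new graph (the input is never mutated). For each pruned layer
#' the convolution keeps only the kept output filters, its batch-norm layer
#' keeps the matching affine entries and running statistics, and the next
#' convolution in the block keeps only the matching input slices. Block
#' output widths, shortcuts and downsample projections are untouched, so the
#' pruned graph always passes [validate_graph()].
#'
#' @param graph a bottleneck-family `model_graph`.
#' @param plan a `prune_plan` built for a graph with the same layer names
#'   and widths.
#' @return the pruned `model_graph`.
#' @export
apply_prune <- function(graph, plan) {
  stopifnot(inherits(plan, "prune_plan"))
  known <- prunable_layers(graph)
  bad <- setdiff(names(plan$entries), known)
  if (length(bad))
    stop("plan references layers absent from the graph: ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (i in seq_along(graph$blocks)) {
    blk <- graph$blocks[[i]]
    if (inherits(blk$conv1, "ghost_conv") || inherits(blk$conv2, "ghost_conv"))
      stop("block '", blk$name, "' already carries ghost modules; ",
           "prune before ghost decomposition", call. = FALSE)
    e1 <- plan$entries[[paste0(blk$name, ".conv1")]]
    e2 <- plan$entries[[paste0(blk$name, ".conv2")]]
    if (!is.null(e1)) {
      if (max(e1$kept) > blk$conv1$c_out || min(e1$kept) < 1L)
        stop("plan kept indices out of range for ", e1$layer, call. = FALSE)
      blk$conv1 <- subset_conv_out(blk$conv1, e1$kept)
      blk$bn1 <- subset_bn(blk$bn1, e1$kept)
      blk$conv2 <- subset_conv_in(blk$conv2, e1$kept)
    }
    if (!is.null(e2)) {
      if (max(e2$kept) > blk$conv2$c_out || min(e2$kept) < 1L)
        stop("plan kept indices out of range for ", e2$layer, call. = FALSE)
      blk$conv2 <- subset_conv_out(blk$conv2, e2$kept)
      blk$bn2 <- subset_bn(blk$bn2, e2$kept)
      blk$conv3 <- subset_conv_in(blk$conv3, e2$kept)
    }
    graph$blocks[[i]] <- bottleneck_spec(blk$name, blk$conv1, blk$bn1,
                                         blk$conv2, blk$bn2, blk$conv3,
                                         blk$bn3, blk$downsample)
  }
  rates <- vapply(plan$entries, `[[`, numeric(1), "rate")
  graph$metadata$transforms <- c(
    graph$metadata$transforms,
    sprintf("prune(%s)", if (length(unique(rates)) == 1L)
      sprintf("rate=%.2g", rates[[1]]) else "per-layer"))
  validate_graph(graph)
}

#' Sparsity-regularized loss
#'
#' Adds an L1 penalty on the batch-norm scale factors to a task loss:
#' `task_loss + gamma * sum(|scales|)`. This is the training objective of
#' the sparsity-trained slimming baseline; the per-layer magnitude pruner
#' itself needs no sparsity pre-training.
#'
#' @param task_loss scalar task loss (e.g. cross-entropy).
#' @param scales numeric vector of batch-norm scale factors, e.g. from
#'   [all_bn_scales()].
#' @param gamma non-negative penalty coefficient.
#' @return the penalized scalar loss.
#' @examples
#' sparsity_loss(1, c(0.5, -0.5), gamma = 0.1)  # 1.1
#' @export
sparsity_loss <- function(task_loss, scales, gamma) {
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  task_loss + gamma * sum(abs(scales))
}

#' Read or write a pruning plan as YAML
#'
#' The plan file lists, per layer, the rate and the kept 1-based channel
#' indices, so a pruning run is fully reproducible from the plan alone.
#'
#' @param plan a `prune_plan`.
#' @param path file path.
#' @return `read_plan` returns a `prune_plan`; `write_plan` returns `path`
#'   invisibly.
#' @export
write_plan <- function(plan, path) {
  yaml::write_yaml(list(rounding = plan$rounding,
                        entries = lapply(unname(plan$entries), function(e)
                          list(layer = e$layer, rate = e$rate,
                               kept = as.integer(e$kept)))),
                   path)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  raw <- yaml::read_yaml(path)
  entries <- lapply(raw$entries, function(e)
    list(layer = e$layer, rate = as.numeric(e$rate),
         kept = sort(as.integer(e$kept))))
  names(entries) <- vapply(entries, `[[`, character(1), "layer")
  structure(list(entries = entries, rounding = raw$rounding %||% "round"),
            class = "prune_plan")
}
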