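# Parameter, FLOP and multiply-add accounting. Convention (calibrated
# against the standard 224x224 ResNet50 budget of ~4.12 GFLOPs): one
# multiply-accumulate counts as one FLOP; batch-norm, activations, pooling
# windows and residual additions count one FLOP per output element; MAdd
# counts multiplies and adds separately, i.e. two per MAC plus the same
# elementwise terms.

flops_conv <- function(c_in, c_out, k_h, k_w, h_out, w_out, groups = 1L) {
  h_out * w_out * c_out * (c_in / groups) * k_h * k_w
}

conv_out_hw <- function(h, w, spec) {
  c((h + 2L * spec$padding - spec$k_h) %/% spec$stride + 1L,
    (w + 2L * spec$padding - spec$k_w) %/% spec$stride + 1L)
}

lt_row <- function(name, kind, params, flops, madd, h = NA, w = NA) {
  data.frame(layer = name, kind = kind, params = params, flops = flops,
             madd = madd, h_out = h, w_out = w, stringsAsFactors = FALSE)
}

conv_rows <- function(spec, h, w) {
  if (inherits(spec, "ghost_conv")) {
    hw <- conv_out_hw(h, w, spec$primary)
    pr <- spec$primary
    ch <- spec$cheap
    rbind(
      lt_row(pr$name, "conv", n_params(pr),
             flops_conv(pr$c_in, pr$c_out, pr$k_h, pr$k_w, hw[1], hw[2]),
             2 * flops_conv(pr$c_in, pr$c_out, pr$k_h, pr$k_w, hw[1], hw[2]),
             hw[1], hw[2]),
      lt_row(ch$name, "conv", n_params(ch),
             flops_conv(ch$c_in, ch$c_out, ch$k_h, ch$k_w, hw[1], hw[2],
                        ch$groups),
             2 * flops_conv(ch$c_in, ch$c_out, ch$k_h, ch$k_w, hw[1], hw[2],
                            ch$groups),
             hw[1], hw[2]))
  } else {
    hw <- conv_out_hw(h, w, spec)
    f <- flops_conv(spec$c_in, spec$c_out, spec$k_h, spec$k_w, hw[1], hw[2],
                    spec$groups)
    lt_row(spec$name, "conv", n_params(spec), f, 2 * f, hw[1], hw[2])
  }
}

elt_row <- function(name, kind, c, h, w, params = 0) {
  e <- h * w * c
  lt_row(name, kind, params, e, e, h, w)
}

#' Per-layer accounting table
#'
#' Walks a graph at its `input_shape`, propagating spatial sizes, and
#' returns one row per primitive operation with its parameter count, FLOPs
#' and MAdd. Ghost modules contribute two convolution rows (primary and
#' cheap).
#'
#' @param graph a `model_graph`.
#' @return a `data.frame` with columns `layer`, `kind`, `params`, `flops`,
#'   `madd`, `h_out`, `w_out`.
#' @export
layer_table <- function(graph) {
  if (is.null(graph$input_shape) || any(graph$input_shape <= 0))
    stop("graph has no valid input_shape", call. = FALSE)
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  if (graph$family == "bottleneck") {
    h <- graph$input_shape[2]; w <- graph$input_shape[3]
    add(conv_rows(graph$stem$conv, h, w))
    hw <- conv_out_hw(h, w, graph$stem$conv); h <- hw[1]; w <- hw[2]
    cbn <- graph$stem$bn$c
    add(elt_row("stem.bn", "bn", cbn, h, w, params = 2 * cbn))
    add(elt_row("stem.relu", "act", cbn, h, w))
    if (graph$stem_pool) {
      h <- (h + 2L - 3L) %/% 2L + 1L
      w <- (w + 2L - 3L) %/% 2L + 1L
      add(elt_row("stem.maxpool", "pool", cbn, h, w))
    }
    for (blk in graph$blocks) {
      h_in <- h; w_in <- w
      add(conv_rows(blk$conv1, h, w))
      hw <- conv_out_hw(h, w,
                        if (inherits(blk$conv1, "ghost_conv"))
                          blk$conv1$primary else blk$conv1)
      h <- hw[1]; w <- hw[2]
      add(elt_row(blk$bn1$name, "bn", blk$bn1$c, h, w, 2 * blk$bn1$c))
      add(elt_row(paste0(blk$name, ".relu1"), "act", blk$bn1$c, h, w))
      add(conv_rows(blk$conv2, h, w))
      hw <- conv_out_hw(h, w,
                        if (inherits(blk$conv2, "ghost_conv"))
                          blk$conv2$primary else blk$conv2)
      h <- hw[1]; w <- hw[2]
      add(elt_row(blk$bn2$name, "bn", blk$bn2$c, h, w, 2 * blk$bn2$c))
      add(elt_row(paste0(blk$name, ".relu2"), "act", blk$bn2$c, h, w))
      add(conv_rows(blk$conv3, h, w))
      add(elt_row(blk$bn3$name, "bn", blk$bn3$c, h, w, 2 * blk$bn3$c))
      if (!is.null(blk$downsample)) {
        add(conv_rows(blk$downsample$conv, h_in, w_in))
        add(elt_row(blk$downsample$bn$name, "bn", blk$downsample$bn$c, h, w,
                    2 * blk$downsample$bn$c))
      }
      cout <- out_channels(blk$conv3)
      add(elt_row(paste0(blk$name, ".add"), "add", cout, h, w))
      add(elt_row(paste0(blk$name, ".relu_out"), "act", cout, h, w))
    }
    add(elt_row("avgpool", "pool", graph$head$in_features, h, w))
  } else {
    for (row in graph$layers) {
      if (row$kind == "conv") {
        # flat rows carry their own output spatial size
        sp <- row$spec
        f <- flops_conv(sp$c_in, sp$c_out, sp$k_h, sp$k_w, row$h, row$w,
                        sp$groups)
        add(lt_row(sp$name, "conv", n_params(sp), f, 2 * f, row$h, row$w))
      } else if (row$kind == "bn") {
        add(elt_row(row$name, "bn", row$spec$c, row$h, row$w,
                    2 * row$spec$c))
      } else {
        add(elt_row(row$name, row$kind, row$c, row$h, row$w))
      }
    }
    fh <- graph$final_hw
    add(elt_row("avgpool", "pool", graph$head$in_features, fh[1], fh[2]))
  }
  hd <- graph$head
  f <- hd$in_features * hd$num_classes
  add(lt_row("fc", "linear", hd$in_features * hd$num_classes + hd$num_classes,
             f, 2 * f))
  do.call(rbind, rows)
}

#' Closed-form parameter count of a pruned convolution layer
#'
#' Evaluates the per-layer count
#' `K_h * K_w * C_in * k + k`, where `k` is the surviving output-channel
#' count at pruning rate `lambda` under the pruner's rounding rule. The
#' trailing `+ k` term is the per-surviving-channel affine (bias-like)
#' parameter; for a convolution built with `has_bias = TRUE` this equals
#' the direct array-size count exactly.
#'
#' @param c_in,c_out,k_h,k_w layer dimensions.
#' @param lambda pruning rate in `[0, 1)`.
#' @param rounding survivor rounding rule (see [make_plan()]).
#' @return integer-valued parameter count.
#' @examples
#' layer_params_pruned(3, 64, 7, 7, 0)     # 9472
#' layer_params_pruned(64, 64, 3, 3, 0.5)  # 18464
#' @export
layer_params_pruned <- function(c_in, c_out, k_h, k_w, lambda,
                                rounding = c("round", "floor")) {
  if (lambda < 0 || lambda >= 1)
    stop("lambda must lie in [0, 1)", call. = FALSE)
  k <- kept_count(c_out, lambda, match.arg(rounding))
  k_h * k_w * c_in * k + k
}

#' Parameter count of a ghost-decomposed layer
#'
#' The shape-derived count of a ghost module with `p_out` total output maps
#' (after any pruning): a primary convolution producing
#' `m = ceiling(p_out / s)` maps plus bias-free depthwise `d x d` cheap
#' kernels for the remaining `p_out - m`. The literal closed form
#' `K_h*K_w*C_in*p_out*(n-s)/n + p_out*(1+s/n)` is attached as attribute
#' `"closed_form"`; it does not dimensionally match a depthwise cheap
#' implementation for general `d`, so the shape-derived count is the
#' authoritative one and any discrepancy is visible rather than hidden.
#'
#' @param c_in,k_h,k_w primary-convolution dimensions.
#' @param p_out total output maps of the module.
#' @param s ghost ratio.
#' @param n total output features of the layer (equals `p_out` once pruning
#'   has been resolved); used by the closed form.
#' @param d cheap kernel size.
#' @return shape-derived count with attribute `closed_form`.
#' @examples
#' layer_params_ghost(16, 3, 3, p_out = 64, s = 2, n = 64, d = 3)  # 4896
#' @export
layer_params_ghost <- function(c_in, k_h, k_w, p_out, s, n = p_out, d = 3) {
  if (n < s) stop("degenerate ghost layer: n < s", call. = FALSE)
  m <- ceiling(p_out / s)
  shape_derived <- k_h * k_w * c_in * m + d * d * (p_out - m)
  closed <- k_h * k_w * c_in * p_out * (n - s) / n + p_out * (1 + s / n)
  structure(shape_derived, closed_form = closed)
}

#' Account a graph's cost
#'
#' Builds the per-layer table and totals for one forward pass at the
#' graph's `input_shape`.
#'
#' @param graph a `model_graph` with a valid `input_shape`.
#' @param baseline optional baseline `model_graph`; when given, reduction
#'   percentages `100 * (1 - compressed / baseline)` are included.
#' @return an object of class `compression_report`: list with `rows`
#'   (data.frame), `totals` (params, flops, madd), and optionally
#'   `baseline` and `pruned_pct`.
#' @examples
#' r <- count_flops(build_resnet50(2, init = FALSE))
#' r$totals$flops / 1e9   # ~4.11 GFLOPs
#' @export
count_flops <- function(graph, baseline = NULL) {
  rows <- layer_table(graph)
  totals <- list(params = sum(rows$params), flops = sum(rows$flops),
                 madd = sum(rows$madd))
  rep <- structure(list(rows = rows, totals = totals,
                        model = graph$metadata$name %||% "model",
                        transforms = graph$metadata$transforms),
                   class = "compression_report")
  if (!is.null(baseline)) {
    brows <- layer_table(baseline)
    bt <- list(params = sum(brows$params), flops = sum(brows$flops),
               madd = sum(brows$madd))
    if (bt$params == 0 || bt$flops == 0)
      stop("baseline graph has zero totals", call. = FALSE)
    rep$baseline <- bt
    rep$pruned_pct <- list(
      params = 100 * (1 - totals$params / bt$params),
      flops = 100 * (1 - totals$flops / bt$flops))
  }
  rep
}

#' Compare a compressed graph against its baseline
#'
#' @param baseline,compressed `model_graph` objects sharing an input shape.
#' @return a `compression_report` with reduction percentages.
#' @export
compression_report <- function(baseline, compressed) {
  count_flops(compressed, baseline = baseline)
}

#' @export
print.compression_report <- function(x, ...) {
  cat("<compression_report> ", x$model, "\n", sep = "")
  if (length(x$transforms))
    cat("  transforms: ", paste(x$transforms, collapse = " -> "), "\n",
        sep = "")
  cat(sprintf("  parameters: %s  (%.3f M)\n",
              format(x$totals$params, big.mark = ","),
              x$totals$params / 1e6))
  cat(sprintf("  FLOPs:      %s  (%.3f G, one MAC = one FLOP)\n",
              format(x$totals$flops, big.mark = ","),
              x$totals$flops / 1e9))
  cat(sprintf("  MAdd:       %.3f G\n", x$totals$madd / 1e9))
  if (!is.null(x$pruned_pct))
    cat(sprintf("  vs baseline: params -%.2f%%, FLOPs -%.2f%%\n",
                x$pruned_pct$params, x$pruned_pct$flops))
  invisible(x)
}

#' Write a compression report to CSV and/or JSON
#'
#' The CSV holds one row per layer plus a `TOTAL` row; the JSON mirrors the
#' full report object.
#'
#' @param report a `compression_report`.
#' @param csv,json output paths (`NULL` to skip either).
#' @return the report, invisibly.
#' @export
write_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) {
    rows <- report$rows
    total <- data.frame(layer = "TOTAL", kind = "total",
                        params = report$totals$params,
                        flops = report$totals$flops,
                        madd = report$totals$madd, h_out = NA, w_out = NA)
    utils::write.csv(rbind(rows, total), csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(model = report$model, transforms = report$transforms,
           totals = report$totals, baseline = report$baseline,
           pruned_pct = report$pruned_pct, rows = report$rows),
      json, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  }
  invisible(report)
}
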