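# Structural YAML serialization of model graphs. The files describe every
# layer's shape fields (not its weights), which is what compression plans,
# reports and reproducibility need: a graph reloaded from YAML re-derives
# identical parameter/FLOP accounting, and can be re-initialized from a
# seed for training.

conv_to_list <- function(cv) {
  if (inherits(cv, "ghost_conv")) {
    list(type = "ghost_conv", name = cv$name, n = cv$n, s = cv$s, d = cv$d,
         primary = conv_to_list(cv$primary), cheap = conv_to_list(cv$cheap))
  } else {
    list(type = "conv", name = cv$name, c_in = cv$c_in, c_out = cv$c_out,
         k_h = cv$k_h, k_w = cv$k_w, stride = cv$stride,
         padding = cv$padding, groups = cv$groups, has_bias = cv$has_bias)
  }
}

conv_from_list <- function(l, init = FALSE) {
  if (identical(l$type, "ghost_conv")) {
    structure(list(name = l$name,
                   primary = conv_from_list(l$primary, init),
                   cheap = conv_from_list(l$cheap, init),
                   n = as.integer(l$n), s = as.integer(l$s),
                   d = as.integer(l$d)),
              class = "ghost_conv")
  } else {
    conv_spec(l$name, l$c_in, l$c_out, l$k_h, l$k_w, l$stride, l$padding,
              l$groups, isTRUE(l$has_bias), init = init)
  }
}

bn_to_list <- function(bn) list(type = "bn", name = bn$name, c = bn$c)
bn_from_list <- function(l) bn_spec(l$name, l$c)

#' Serialize a model graph to YAML
#'
#' Writes the graph's complete structural description -- every
#' convolution's shape fields (including ghost primary/cheap parts),
#' batch-norm widths, head size, input shape and the applied-transform
#' provenance -- as a diffable YAML document. Weights are not serialized;
#' [graph_from_yaml()] rebuilds the structure (optionally re-initializing
#' weights from a seed), which is sufficient for all accounting.
#'
#' @param graph a `model_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
graph_to_yaml <- function(graph, path) {
  doc <- list(family = graph$family,
              name = graph$metadata$name,
              input_shape = as.integer(graph$input_shape),
              transforms = as.list(graph$metadata$transforms),
              head = list(in_features = graph$head$in_features,
                          num_classes = graph$head$num_classes))
  if (graph$family == "bottleneck") {
    doc$stem <- list(conv = conv_to_list(graph$stem$conv),
                     bn = bn_to_list(graph$stem$bn))
    doc$stem_pool <- graph$stem_pool
    doc$blocks <- lapply(graph$blocks, function(blk) {
      b <- list(name = blk$name,
                conv1 = conv_to_list(blk$conv1), bn1 = bn_to_list(blk$bn1),
                conv2 = conv_to_list(blk$conv2), bn2 = bn_to_list(blk$bn2),
                conv3 = conv_to_list(blk$conv3), bn3 = bn_to_list(blk$bn3))
      if (!is.null(blk$downsample))
        b$downsample <- list(conv = conv_to_list(blk$downsample$conv),
                             bn = bn_to_list(blk$downsample$bn))
      b
    })
  } else {
    doc$final_hw <- as.integer(graph$final_hw)
    doc$layers <- lapply(graph$layers, function(row) {
      out <- list(kind = row$kind, name = row$name, h = row$h, w = row$w)
      if (row$kind == "conv") out$spec <- conv_to_list(row$spec)
      else if (row$kind == "bn") out$spec <- bn_to_list(row$spec)
      else out$c <- row$c
      out
    })
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Rebuild a model graph from YAML
#'
#' @param path a file written by [graph_to_yaml()].
#' @param init re-initialize weight arrays (He-uniform, current RNG
#'   stream); with the default `FALSE` the graph is shape-only.
#' @return a `model_graph`.
#' @export
graph_from_yaml <- function(path, init = FALSE) {
  doc <- yaml::read_yaml(path)
  head <- make_head(doc$head$in_features, doc$head$num_classes, init = init)
  meta <- list(name = doc$name,
               transforms = as.character(unlist(doc$transforms)))
  if (doc$family == "bottleneck") {
    blocks <- lapply(doc$blocks, function(b) {
      ds <- if (!is.null(b$downsample))
        list(conv = conv_from_list(b$downsample$conv, init),
             bn = bn_from_list(b$downsample$bn))
      bottleneck_spec(b$name,
                      conv_from_list(b$conv1, init), bn_from_list(b$bn1),
                      conv_from_list(b$conv2, init), bn_from_list(b$bn2),
                      conv_from_list(b$conv3, init), bn_from_list(b$bn3),
                      downsample = ds)
    })
    g <- model_graph("bottleneck",
                     stem = list(conv = conv_from_list(doc$stem$conv, init),
                                 bn = bn_from_list(doc$stem$bn)),
                     stem_pool = isTRUE(doc$stem_pool), blocks = blocks,
                     head = head, input_shape = unlist(doc$input_shape),
                     metadata = meta)
  } else {
    layers <- lapply(doc$layers, function(row) {
      out <- list(kind = row$kind, name = row$name, h = row$h, w = row$w)
      if (row$kind == "conv") out$spec <- conv_from_list(row$spec, init)
      else if (row$kind == "bn") out$spec <- bn_from_list(row$spec)
      else out$c <- row$c
      out
    })
    g <- model_graph("flat", layers = layers, head = head,
                     input_shape = unlist(doc$input_shape),
                     final_hw = unlist(doc$final_hw), metadata = meta)
  }
  validate_graph(g)
}
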