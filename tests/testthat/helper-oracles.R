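# Shared fixtures and independent oracles.

# Brute-force trainable-parameter count: recursively walks the raw list
# structure and sums the length of every parameter array by field name,
# independently of n_params().
brute_count <- function(x) {
  if (!is.list(x)) return(0)
  s <- 0
  nms <- names(x)
  for (i in seq_along(x)) {
    nm <- if (is.null(nms)) "" else nms[i]
    if (nm %in% c("weights", "bias", "scale", "shift", "W", "b")) {
      s <- s + length(x[[i]])
    } else if (is.list(x[[i]])) {
      s <- s + brute_count(x[[i]])
    }
  }
  s
}

# Brute-force k-largest-|scale| selection with the same tie rule as the
# pruner (ties resolved toward higher channel index).
oracle_kept <- function(scale, k) {
  ord <- order(abs(scale), seq_along(scale))
  sort(ord[(length(scale) - k + 1):length(scale)])
}

tiny_graph <- function(widths = c(8L, 16L), blocks = c(1L, 1L), size = 16L,
                       classes = 2L, seed = 1L) {
  build_tiny_resnet(classes, widths, blocks, c(3L, size, size), seed = seed)
}

rand_input <- function(size, n = 2L, channels = 3L, seed = 99L) {
  set.seed(seed)
  array(stats::rnorm(size * size * channels * n), c(size, size, channels, n))
}

small_train_config <- function(epochs, lr = 0.08, seed = 1L, ...) {
  train_config(epochs = epochs, batch_size = 32L, lr = lr, repeats = 1L,
               seed = seed, augment = FALSE, ...)
}
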