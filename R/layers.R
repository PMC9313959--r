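# Dense-array forward/backward primitives for the desk-scale training
# engine. Activations are 4-D arrays laid out (H, W, C, N); convolution is
# implemented by im2col + BLAS matrix multiplication, which is the fastest
# pure-R route at the batch and image sizes this package trains at.

pad_hw <- function(x, p, fill = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(fill, dim = c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , ] <- x
  out
}

conv2d_fwd <- function(x, w, b = NULL, stride = 1L, padding = 0L,
                       groups = 1L, keep = FALSE) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  wd <- dim(w); Co <- wd[1]; Cg <- wd[2]; Kh <- wd[3]; Kw <- wd[4]
  if (C != Cg * groups)
    stop("conv2d: input has ", C, " channels, weights expect ", Cg * groups,
         call. = FALSE)
  Ho <- (H + 2L * padding - Kh) %/% stride + 1L
  Wo <- (W + 2L * padding - Kw) %/% stride + 1L
  xp <- pad_hw(x, padding)
  Cog <- Co %/% groups
  y <- array(0, c(Ho, Wo, Co, N))
  cols <- if (keep) vector("list", groups)
  for (g in seq_len(groups)) {
    ci <- ((g - 1L) * Cg + 1L):(g * Cg)
    co <- ((g - 1L) * Cog + 1L):(g * Cog)
    col <- array(0, c(Cg, Kh, Kw, Ho, Wo, N))
    for (kh in seq_len(Kh)) for (kw in seq_len(Kw)) {
      rs <- kh + stride * (0:(Ho - 1L))
      cs <- kw + stride * (0:(Wo - 1L))
      patch <- xp[rs, cs, ci, , drop = FALSE]
      dim(patch) <- c(Ho, Wo, Cg, N)
      col[, kh, kw, , , ] <- aperm(patch, c(3, 1, 2, 4))
    }
    dim(col) <- c(Cg * Kh * Kw, Ho * Wo * N)
    wsub <- w[co, , , , drop = FALSE]
    wm <- matrix(wsub, nrow = Cog)
    ym <- wm %*% col
    if (!is.null(b)) ym <- ym + b[co]
    ya <- array(ym, c(Cog, Ho, Wo, N))
    y[, , co, ] <- aperm(ya, c(2, 3, 1, 4))
    if (keep) cols[[g]] <- col
  }
  cache <- if (keep)
    list(cols = cols, w = w, x_dim = d, stride = stride, padding = padding,
         groups = groups, out_dim = c(Ho, Wo, Co, N),
         has_bias = !is.null(b))
  list(y = y, cache = cache)
}

conv2d_bwd <- function(dy, cache) {
  w <- cache$w
  wd <- dim(w); Co <- wd[1]; Cg <- wd[2]; Kh <- wd[3]; Kw <- wd[4]
  d <- cache$x_dim; H <- d[1]; W <- d[2]; N <- d[4]
  stride <- cache$stride; p <- cache$padding; G <- cache$groups
  od <- cache$out_dim; Ho <- od[1]; Wo <- od[2]
  Cog <- Co %/% G
  dxp <- array(0, c(H + 2L * p, W + 2L * p, d[3], N))
  dw <- array(0, dim = wd)
  db <- if (cache$has_bias) numeric(Co) else NULL
  for (g in seq_len(G)) {
    ci <- ((g - 1L) * Cg + 1L):(g * Cg)
    co <- ((g - 1L) * Cog + 1L):(g * Cog)
    dys <- dy[, , co, , drop = FALSE]
    dim(dys) <- c(Ho, Wo, Cog, N)
    dym <- aperm(dys, c(3, 1, 2, 4))
    dim(dym) <- c(Cog, Ho * Wo * N)
    col <- cache$cols[[g]]
    dw[co, , , ] <- array(dym %*% t(col), c(Cog, Cg, Kh, Kw))
    if (cache$has_bias) db[co] <- rowSums(dym)
    wm <- matrix(w[co, , , , drop = FALSE], nrow = Cog)
    dcol <- crossprod(wm, dym)
    dim(dcol) <- c(Cg, Kh, Kw, Ho, Wo, N)
    for (kh in seq_len(Kh)) for (kw in seq_len(Kw)) {
      rs <- kh + stride * (0:(Ho - 1L))
      cs <- kw + stride * (0:(Wo - 1L))
      sl <- dcol[, kh, kw, , , , drop = FALSE]
      dim(sl) <- c(Cg, Ho, Wo, N)
      cur <- dxp[rs, cs, ci, , drop = FALSE]
      dxp[rs, cs, ci, ] <- cur + aperm(sl, c(2, 3, 1, 4))
    }
  }
  dx <- if (p > 0L)
    dxp[(p + 1L):(p + H), (p + 1L):(p + W), , , drop = FALSE] else dxp
  dim(dx) <- d
  list(dx = dx, dw = dw, db = db)
}

# Batch normalization. Training mode normalizes with batch statistics
# (biased variance, as is standard) and updates the running mean/sd with
# momentum; evaluation mode uses the stored running statistics.
bn_fwd <- function(x, bn, train = FALSE, keep = FALSE, momentum = 0.1) {
  d <- dim(x); C <- d[3]
  n <- d[1] * d[2] * d[4]
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(n, C)
  if (train) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = n)
    v <- colMeans(xc * xc)
    bn$mean <- (1 - momentum) * bn$mean + momentum * mu
    vu <- if (n > 1L) v * n / (n - 1L) else v
    bn$sd <- sqrt((1 - momentum) * bn$sd^2 + momentum * vu)
  } else {
    mu <- bn$mean
    v <- bn$sd^2
    xc <- xm - rep(mu, each = n)
  }
  inv <- 1 / sqrt(v + bn$eps)
  xhat <- xc * rep(inv, each = n)
  ym <- xhat * rep(bn$scale, each = n) + rep(bn$shift, each = n)
  dim(ym) <- c(d[1], d[2], d[4], C)
  y <- aperm(ym, c(1, 2, 4, 3))
  cache <- if (keep)
    list(xhat = xhat, inv = inv, dims = d, scale = bn$scale, train = train)
  list(y = y, bn = bn, cache = cache)
}

bn_bwd <- function(dy, cache) {
  d <- cache$dims; C <- d[3]
  n <- d[1] * d[2] * d[4]
  dym <- aperm(dy, c(1, 2, 4, 3))
  dim(dym) <- c(n, C)
  xhat <- cache$xhat
  dscale <- colSums(dym * xhat)
  dshift <- colSums(dym)
  dxhat <- dym * rep(cache$scale, each = n)
  if (cache$train) {
    dxm <- (dxhat - rep(colMeans(dxhat), each = n) -
              xhat * rep(colMeans(dxhat * xhat), each = n)) *
      rep(cache$inv, each = n)
  } else {
    dxm <- dxhat * rep(cache$inv, each = n)
  }
  dim(dxm) <- c(d[1], d[2], d[4], C)
  list(dx = aperm(dxm, c(1, 2, 4, 3)), dscale = dscale, dshift = dshift)
}

relu_fwd <- function(x, keep = FALSE) {
  y <- x
  y[y < 0] <- 0
  list(y = y, cache = if (keep) (x > 0))
}

relu_bwd <- function(dy, mask) dy * mask

maxpool_fwd <- function(x, k = 3L, stride = 2L, padding = 1L, keep = FALSE) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Ho <- (H + 2L * padding - k) %/% stride + 1L
  Wo <- (W + 2L * padding - k) %/% stride + 1L
  xp <- pad_hw(x, padding, fill = -Inf)
  best <- array(-Inf, c(Ho, Wo, C, N))
  arg <- array(0L, c(Ho, Wo, C, N))
  idx <- 0L
  for (kh in seq_len(k)) for (kw in seq_len(k)) {
    idx <- idx + 1L
    rs <- kh + stride * (0:(Ho - 1L))
    cs <- kw + stride * (0:(Wo - 1L))
    sl <- xp[rs, cs, , , drop = FALSE]
    dim(sl) <- c(Ho, Wo, C, N)
    upd <- sl > best
    best[upd] <- sl[upd]
    arg[upd] <- idx
  }
  cache <- if (keep)
    list(arg = arg, x_dim = d, k = k, stride = stride, padding = padding,
         out_dim = c(Ho, Wo, C, N))
  list(y = best, cache = cache)
}

maxpool_bwd <- function(dy, cache) {
  d <- cache$x_dim; H <- d[1]; W <- d[2]; N <- d[4]
  p <- cache$padding; k <- cache$k; stride <- cache$stride
  od <- cache$out_dim; Ho <- od[1]; Wo <- od[2]
  dxp <- array(0, c(H + 2L * p, W + 2L * p, d[3], N))
  idx <- 0L
  for (kh in seq_len(k)) for (kw in seq_len(k)) {
    idx <- idx + 1L
    rs <- kh + stride * (0:(Ho - 1L))
    cs <- kw + stride * (0:(Wo - 1L))
    dxp[rs, cs, , ] <- dxp[rs, cs, , , drop = FALSE] + dy * (cache$arg == idx)
  }
  dx <- if (p > 0L)
    dxp[(p + 1L):(p + H), (p + 1L):(p + W), , , drop = FALSE] else dxp
  dim(dx) <- d
  dx
}

# Global average pooling: (H, W, C, N) -> (C, N)
gap_fwd <- function(x, keep = FALSE) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  y <- matrix(colMeans(xm), d[3], d[4])
  list(y = y, cache = if (keep) d)
}

gap_bwd <- function(dy, d) {
  hw <- d[1] * d[2]
  array(rep(as.vector(dy) / hw, each = hw), dim = d)
}

linear_fwd <- function(x, W, b, keep = FALSE) {
  list(y = W %*% x + b, cache = if (keep) x)
}

linear_bwd <- function(dy, x, W) {
  list(dx = crossprod(W, dy), dW = dy %*% t(x), db = rowSums(dy))
}

# Softmax cross-entropy, mean over the batch.
# logits: (num_classes, N); labels: 0-based integer vector.
softmax_ce <- function(logits, labels) {
  K <- nrow(logits); N <- ncol(logits)
  z <- logits - rep(apply(logits, 2, max), each = K)
  e <- exp(z)
  p <- e / rep(colSums(e), each = K)
  at <- cbind(labels + 1L, seq_len(N))
  loss <- -mean(log(pmax(p[at], 1e-12)))
  dz <- p
  dz[at] <- dz[at] - 1
  list(loss = loss, dlogits = dz / N, prob = p)
}
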