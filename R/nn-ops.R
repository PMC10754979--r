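# Low-level network operations.
#
# Activation tensors are arrays [C, W, H, N]: feature channels, temporal
# extent, spatial extent (electrodes), batch. Every convolution in the
# architecture is one-dimensional — either along time (1 x k kernels) or
# across electrodes (k x 1 kernels) — implemented in compiled code as an
# im2col gather plus one GEMM against the [C_out, C_in * k] reshaped
# kernel (see src/tspnet_core.cpp); batch normalization and the
# similarity-loop of the time-spatial head are compiled as well.

.as_cwhn_matrix <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1L], prod(d[-1L]))
  x
}

# Same-padded stride-1 convolution along one axis.
# x: [Ci, W, H, N]; w: [Co, Ci, k] (k odd). Returns [Co, W, H, N].
conv_axis_forward <- function(x, w, axis = 2L) {
  k <- dim(w)[3L]
  if (k %% 2L == 0L) stop("convolution kernels must be odd-sized")
  if (dim(w)[2L] != dim(x)[1L]) {
    stop("kernel input channels do not match activation")
  }
  cpp_conv_fwd(x, w, axis)
}

# Backward of conv_axis_forward. dy: [Co, W, H, N]. Returns list(dx, dw).
conv_axis_backward <- function(dy, x, w, axis = 2L) {
  cpp_conv_bwd(dy, x, w, axis)
}

# 1x1 projection (pure channel mixing), used for residual skips.
proj_forward <- function(x, w) {
  d <- dim(x)
  out <- w %*% .as_cwhn_matrix(x)
  dim(out) <- c(nrow(w), d[2L], d[3L], d[4L])
  out
}

proj_backward <- function(dy, x, w) {
  d <- dim(x)
  dym <- .as_cwhn_matrix(dy)
  dw <- tcrossprod(dym, .as_cwhn_matrix(x))
  dx <- crossprod(w, dym)
  dim(dx) <- d
  list(dx = dx, dw = dw)
}

# Batch normalization over (W, H, N) per feature channel.
# Training mode uses batch statistics and updates running estimates;
# evaluation mode uses the running estimates (deterministic).
bn_forward <- function(x, g, b, state, train, eps = 1e-5, momentum = 0.1) {
  r <- cpp_bn_fwd(x, dim(x)[1L], g, b, state$mean, state$var,
                  train, momentum, eps)
  list(y = r$y, state = list(mean = r$rmean, var = r$rvar),
       cache = list(x = x, mu = r$mu, istd = r$istd, g = g, train = train))
}

bn_backward <- function(dy, cache) {
  cpp_bn_bwd(dy, cache$x, cache$mu, cache$istd, cache$g, cache$train)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Spatial max-pooling, size 2 stride 2 along H; an odd trailing electrode is
# dropped (H' = floor(H / 2)). Ties resolve to the first (upper) element.
maxpool_h_forward <- function(x) {
  d <- dim(x)
  h2 <- d[3L] %/% 2L
  if (h2 < 1L) stop("spatial extent < 2: cannot max-pool")
  a <- x[, , seq(1L, 2L * h2, 2L), , drop = FALSE]
  b <- x[, , seq(2L, 2L * h2, 2L), , drop = FALSE]
  take_a <- a >= b
  y <- pmax(a, b)
  dim(y) <- c(d[1L], d[2L], h2, d[4L])
  list(y = y, cache = list(take_a = take_a, d = d, h2 = h2))
}

maxpool_h_backward <- function(dy, cache) {
  d <- cache$d; h2 <- cache$h2
  dx <- array(0, d)
  dx[, , seq(1L, 2L * h2, 2L), ] <- dy * cache$take_a
  dx[, , seq(2L, 2L * h2, 2L), ] <- dy * !cache$take_a
  dx
}

# Subsample H with stride 2 (used by the stride-2 spatial-convolution
# variant); keeps rows 1, 3, 5, ...
subsample_h_forward <- function(x) {
  d <- dim(x)
  idx <- seq(1L, d[3L], 2L)
  list(y = x[, , idx, , drop = FALSE], cache = list(d = d, idx = idx))
}

subsample_h_backward <- function(dy, cache) {
  dx <- array(0, cache$d)
  dx[, , cache$idx, ] <- dy
  dx
}

# Temporal decimation: average pooling along W with window = stride = s,
# where s is the smallest integer making floor(W / s) <= w_max. Identity
# when W <= w_max. Trailing samples that do not fill a window are dropped.
decimation_stride <- function(w, w_max) {
  if (w <= w_max) return(1L)
  s <- 2L
  while (w %/% s > w_max) s <- s + 1L
  s
}

temporal_decimate_forward <- function(x, w_max) {
  d <- dim(x)
  s <- decimation_stride(d[2L], w_max)
  if (s == 1L) {
    return(list(y = x, cache = list(s = 1L, d = d)))
  }
  w2 <- d[2L] %/% s
  y <- array(0, c(d[1L], w2, d[3L], d[4L]))
  for (j in seq_len(s)) {
    y <- y + x[, seq(j, w2 * s, s), , , drop = FALSE]
  }
  y <- y / s
  list(y = y, cache = list(s = s, d = d, w2 = w2))
}

temporal_decimate_backward <- function(dy, cache) {
  if (cache$s == 1L) return(dy)
  dx <- array(0, cache$d)
  for (j in seq_len(cache$s)) {
    dx[, seq(j, cache$w2 * cache$s, cache$s), , ] <- dy / cache$s
  }
  dx
}

# Column-wise softmax with per-column max subtraction.
softmax_cols <- function(m) {
  nr <- nrow(m)
  cm <- m[cbind(max.col(t(m), ties.method = "first"), seq_len(ncol(m)))]
  e <- exp(m - rep(cm, each = nr))
  e / rep(colSums(e), each = nr)
}
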