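# Shared fixtures: tiny configurations and epoch sets built in code.

tiny_model_config <- function(n_input_channels = 4L, ...) {
  tspnet_config(n_input_channels = n_input_channels, n_samples = 12L,
                tdfe_widths = c(2L, 3L, 4L), sdfe_width = 5L,
                w_max = 6L, seed = 2L, ...)
}

tiny_epochs <- function(n_per_class = 2L, n_channels = 4L, n_samples = 12L,
                        fs = 32, seed = 7L) {
  n <- 6L * n_per_class
  set.seed(seed)
  data <- array(rnorm(n * n_channels * n_samples), c(n, n_channels, n_samples))
  epoch_set(data, rep(0:5, each = n_per_class), fs,
            paste0("ch", seq_len(n_channels)))
}

# Small but learnable desk-style conditions used by the training tests.
desk_test_data <- function(effect_size = 3, seed = 11L, n_samples = 48L,
                           trials_per_class = 60L) {
  cfg <- desk_synth_config(effect_size = effect_size, seed = seed,
                           n_samples = n_samples,
                           trials_per_class = trials_per_class)
  generate_epoch_set(cfg)
}

desk_test_model_config <- function(n_samples = 48L, ...) {
  tspnet_config(n_input_channels = 16L, n_samples = n_samples,
                tdfe_widths = c(4L, 8L, 16L), sdfe_width = 16L,
                w_max = 32L, ...)
}

# Independent straight-line oracle for the parallel residual block:
# per-branch direct convolution (nested loops), additive skip,
# batch-statistics normalization of (conv + skip), rectification, summed
# across branches.
naive_conv_axis <- function(x, w, axis) {
  d <- dim(x); co <- dim(w)[1L]; ci <- dim(w)[2L]; k <- dim(w)[3L]
  p <- (k - 1L) %/% 2L
  out <- array(0, c(co, d[2L], d[3L], d[4L]))
  for (n in seq_len(d[4L])) for (h in seq_len(d[3L])) for (wi in seq_len(d[2L])) {
    for (o in seq_len(co)) {
      acc <- 0
      for (i in seq_len(ci)) for (j in seq_len(k)) {
        if (axis == 2L) {
          src <- wi + j - 1L - p
          if (src >= 1L && src <= d[2L]) acc <- acc + w[o, i, j] * x[i, src, h, n]
        } else {
          src <- h + j - 1L - p
          if (src >= 1L && src <= d[3L]) acc <- acc + w[o, i, j] * x[i, wi, src, n]
        }
      }
      out[o, wi, h, n] <- acc
    }
  }
  out
}

naive_bn <- function(x, g, b, eps = 1e-5) {
  co <- dim(x)[1L]
  out <- x
  for (c in seq_len(co)) {
    v <- x[c, , , ]
    mu <- mean(v)
    va <- mean((v - mu)^2)
    out[c, , , ] <- g[c] * (x[c, , , ] - mu) / sqrt(va + eps) + b[c]
  }
  out
}

naive_block <- function(x, weights, axis, residual = TRUE) {
  co <- dim(weights$kernels[[1L]])[1L]
  ci <- dim(x)[1L]
  skip <- NULL
  if (residual) {
    skip <- if (ci == co) x else {
      d <- dim(x)
      s <- array(0, c(co, d[2L], d[3L], d[4L]))
      for (n in seq_len(d[4L])) for (h in seq_len(d[3L])) for (wi in seq_len(d[2L])) {
        s[, wi, h, n] <- weights$proj %*% x[, wi, h, n]
      }
      s
    }
  }
  out <- 0
  for (j in seq_along(weights$kernels)) {
    cv <- naive_conv_axis(x, weights$kernels[[j]], axis)
    if (residual) cv <- cv + skip
    g <- if (is.null(weights$gamma)) rep(1, co) else weights$gamma[[j]]
    b <- if (is.null(weights$beta)) rep(0, co) else weights$beta[[j]]
    z <- naive_bn(cv, g, b)
    out <- out + pmax(z, 0)
  }
  out
}

random_block_weights <- function(ci, co, kernels, seed, proj = (ci != co)) {
  set.seed(seed)
  list(
    kernels = lapply(kernels, function(k) array(rnorm(co * ci * k), c(co, ci, k))),
    gamma = replicate(length(kernels), runif(co, 0.5, 1.5), simplify = FALSE),
    beta = replicate(length(kernels), rnorm(co, sd = 0.2), simplify = FALSE),
    proj = if (proj) matrix(rnorm(co * ci), co, ci) else NULL
  )
}
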