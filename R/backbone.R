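# Network configuration, parameter initialization, and the temporal (TDFE)
# and spatial (SDFE) feature-extraction stages built from parallel residual
# convolutional blocks.

#' Network architecture configuration
#'
#' Collects every architecture hyperparameter and the ablation-variant
#' switches. The reference architecture uses a 1 x 7 temporal stem into three
#' temporal residual stages of widths 64/128/256 (kernels 1 x 1 and 1 x 3 in
#' parallel), a 512-wide spatial stage (kernels 1 x 1, 3 x 1, 5 x 1 in
#' parallel) followed by spatial max-pooling (size 2, stride 2), temporal
#' decimation to at most `w_max` columns, the time-spatial parallel feature
#' extractor, and a global-average-pooled linear softmax head.
#'
#' @param n_input_channels Number of EEG electrodes (spatial extent).
#' @param n_samples Samples per epoch (temporal extent).
#' @param n_classes Number of classes (6).
#' @param stem_kernel Temporal stem kernel length (odd; default 7).
#' @param tdfe_widths Three strictly increasing stage widths.
#' @param tdfe_kernels Temporal kernel lengths of the parallel branches.
#' @param sdfe_width Spatial stage width.
#' @param sdfe_kernels Spatial kernel lengths of the parallel branches.
#' @param w_max Temporal extent cap before the time-spatial head (average
#'   pooling with the smallest stride that brings the extent under the cap).
#' @param use_tdfe,use_sdfe,use_tspfe Ablation switches: drop a stage
#'   entirely.
#' @param tdfe_residual `FALSE` removes the additive skip from the temporal
#'   blocks (the non-residual variant).
#' @param sdfe_pooling_mode `"maxpool"` (default) or `"stride2"` (spatial
#'   stride-2 convolution instead of max-pooling).
#' @param seed Seed used by [tspnet_init()] for weight initialization.
#' @return An object of class `tspnet_config`.
#' @export
tspnet_config <- function(n_input_channels = 16L,
                          n_samples = 1500L,
                          n_classes = 6L,
                          stem_kernel = 7L,
                          tdfe_widths = c(64L, 128L, 256L),
                          tdfe_kernels = c(1L, 3L),
                          sdfe_width = 512L,
                          sdfe_kernels = c(1L, 3L, 5L),
                          w_max = 64L,
                          use_tdfe = TRUE,
                          tdfe_residual = TRUE,
                          use_sdfe = TRUE,
                          sdfe_pooling_mode = c("maxpool", "stride2"),
                          use_tspfe = TRUE,
                          seed = 1L) {
  sdfe_pooling_mode <- match.arg(sdfe_pooling_mode)
  if (length(tdfe_widths) != 3L || any(diff(tdfe_widths) <= 0)) {
    stop("tdfe_widths must be three strictly increasing integers")
  }
  if (any(c(stem_kernel, tdfe_kernels, sdfe_kernels) %% 2L == 0L)) {
    stop("all kernels must be odd-sized")
  }
  if (w_max < 4L) stop("w_max must be >= 4")
  if (n_input_channels < 2L && use_sdfe) {
    stop("spatial extent < 2: cannot use the spatial stage")
  }
  structure(list(
    n_input_channels = as.integer(n_input_channels),
    n_samples = as.integer(n_samples),
    n_classes = as.integer(n_classes),
    stem_kernel = as.integer(stem_kernel),
    tdfe_widths = as.integer(tdfe_widths),
    tdfe_kernels = as.integer(tdfe_kernels),
    sdfe_width = as.integer(sdfe_width),
    sdfe_kernels = as.integer(sdfe_kernels),
    w_max = as.integer(w_max),
    use_tdfe = isTRUE(use_tdfe),
    tdfe_residual = isTRUE(tdfe_residual),
    use_sdfe = isTRUE(use_sdfe),
    sdfe_pooling_mode = sdfe_pooling_mode,
    use_tspfe = isTRUE(use_tspfe),
    seed = as.integer(seed)
  ), class = "tspnet_config")
}

#' Desk-scale architecture configuration
#'
#' A width- and extent-reduced configuration used by the package's own test
#' protocol: the same topology (temporal stem, three parallel-residual
#' temporal stages, three-branch spatial stage with pooling, temporal
#' decimation, time-spatial head) with widths 4/8/16 + 16 and a 32-column
#' temporal cap, sized so that the full training protocol runs on one CPU
#' core. See the methods vignette.
#'
#' @param n_input_channels,n_samples Input geometry (defaults match
#'   [desk_synth_config()]).
#' @param ... Overrides passed to [tspnet_config()].
#' @return A `tspnet_config`.
#' @export
desk_model_config <- function(n_input_channels = 16L, n_samples = 48L, ...) {
  tspnet_config(n_input_channels = n_input_channels, n_samples = n_samples,
                tdfe_widths = c(4L, 8L, 16L), sdfe_width = 16L,
                w_max = 32L, ...)
}

# Channel counts and extents at every stage, given the variant flags.
tspnet_shapes <- function(config) {
  h <- config$n_input_channels
  w <- config$n_samples
  c_stem <- config$tdfe_widths[1L]
  c_tdfe <- if (config$use_tdfe) config$tdfe_widths[3L] else c_stem
  c_sdfe <- if (config$use_sdfe) config$sdfe_width else c_tdfe
  h_sdfe <- if (config$use_sdfe) h %/% 2L else h
  s <- decimation_stride(w, config$w_max)
  w_dec <- if (s == 1L) w else w %/% s
  c_head <- if (config$use_tspfe) 2L * c_sdfe else c_sdfe
  list(stem = c(c_stem, w, h), tdfe = c(c_tdfe, w, h),
       sdfe = c(c_sdfe, w, h_sdfe), decimate = c(c_sdfe, w_dec, h_sdfe),
       tspfe = c(c_head, w_dec, h_sdfe), head_in = c_head,
       decimation_stride = s)
}

.he_init <- function(co, ci, k) {
  array(stats::rnorm(co * ci * k, sd = sqrt(2 / (ci * k))), c(co, ci, k))
}

.init_block <- function(params, state, pf, ci, co, kernels) {
  for (j in seq_along(kernels)) {
    k <- kernels[j]
    params[[sprintf("%s.br%d.W", pf, j)]] <- .he_init(co, ci, k)
    params[[sprintf("%s.br%d.bn.g", pf, j)]] <- rep(1, co)
    params[[sprintf("%s.br%d.bn.b", pf, j)]] <- rep(0, co)
    state[[sprintf("%s.br%d.bn", pf, j)]] <- list(mean = rep(0, co), var = rep(1, co))
  }
  if (ci != co) {
    params[[sprintf("%s.proj.W", pf)]] <-
      matrix(stats::rnorm(co * ci, sd = sqrt(2 / ci)), co, ci)
  }
  list(params = params, state = state)
}

#' Initialize network parameters
#'
#' Builds the full parameter set (He-initialized convolutions, unit-gain
#' batch-norm, identity-initialized orthogonal generator, open gates) and the
#' batch-norm running statistics, deterministically from `config$seed`.
#'
#' @param config A [tspnet_config()].
#' @return A list with elements `params` (flat named list of arrays),
#'   `state` (batch-norm running statistics) and `config`; class
#'   `tspnet_model`.
#' @export
tspnet_init <- function(config) {
  shapes <- tspnet_shapes(config)
  params <- list(); state <- list()
  with_seed(config$seed, {
    c1 <- config$tdfe_widths[1L]
    params[["stem.W"]] <- .he_init(c1, 1L, config$stem_kernel)
    params[["stem.bn.g"]] <- rep(1, c1)
    params[["stem.bn.b"]] <- rep(0, c1)
    state[["stem.bn"]] <- list(mean = rep(0, c1), var = rep(1, c1))
    if (config$use_tdfe) {
      ci <- c1
      for (i in 1:3) {
        co <- config$tdfe_widths[i]
        r <- .init_block(params, state, sprintf("tdfe%d", i), ci, co,
                         config$tdfe_kernels)
        params <- r$params; state <- r$state
        ci <- co
      }
    }
    if (config$use_sdfe) {
      ci <- shapes$tdfe[1L]
      r <- .init_block(params, state, "sdfe", ci, config$sdfe_width,
                       config$sdfe_kernels)
      params <- r$params; state <- r$state
    }
    if (config$use_tspfe) {
      hh <- shapes$sdfe[3L]
      cc <- shapes$sdfe[1L]
      params[["tspfe.A"]] <- matrix(0, hh, hh)
      # small diagonal init keeps the similarity softmax in its responsive
      # range at the start of training (Q entries scale with H * |X|^2 * d)
      params[["tspfe.d"]] <- rep(0.1, hh)
      # gates start exactly open (w = 0, b = 1): the gate pre-activation is
      # then independent of the feature scale at the start of training, so
      # an early negative drift cannot close the rectified gate everywhere
      # (a closed ReLU gate receives no gradient and cannot reopen)
      params[["tspfe.gc.w"]] <- rep(0, cc)
      params[["tspfe.gc.b"]] <- 1
      params[["tspfe.gr.w"]] <- rep(0, cc)
      params[["tspfe.gr.b"]] <- 1
    }
    cin <- shapes$head_in
    # small final-layer init: initial predictions near-uniform, initial
    # loss near log(n_classes)
    params[["head.W"]] <- matrix(stats::rnorm(config$n_classes * cin,
                                              sd = 0.01),
                                 config$n_classes, cin)
    params[["head.b"]] <- rep(0, config$n_classes)
  })
  structure(list(params = params, state = state, config = config),
            class = "tspnet_model")
}

#' @export
print.tspnet_model <- function(x, ...) {
  sh <- tspnet_shapes(x$config)
  np <- sum(vapply(x$params, length, integer(1L)))
  cat(sprintf("<tspnet_model> %d parameters\n", np))
  for (nm in names(sh)[1:5]) {
    cat(sprintf("  %-9s [%s]\n", nm, paste(sh[[nm]], collapse = " x ")))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Parallel residual block: out = sum over branches of
# relu(BN(conv(x, W_b)) + skip(x)), skip = identity (channel counts equal),
# a 1x1 projection otherwise, or absent in the non-residual variant.

.block_forward <- function(params, state, pf, x, axis, residual, train,
                           stride2 = FALSE) {
  nb <- 0L
  while (!is.null(params[[sprintf("%s.br%d.W", pf, nb + 1L)]])) nb <- nb + 1L
  js <- seq_len(nb)
  kernels <- lapply(js, function(j) params[[sprintf("%s.br%d.W", pf, j)]])
  gammas <- lapply(js, function(j) params[[sprintf("%s.br%d.bn.g", pf, j)]])
  betas <- lapply(js, function(j) params[[sprintf("%s.br%d.bn.b", pf, j)]])
  rmeans <- lapply(js, function(j) state[[sprintf("%s.br%d.bn", pf, j)]]$mean)
  rvars <- lapply(js, function(j) state[[sprintf("%s.br%d.bn", pf, j)]]$var)
  projW <- params[[sprintf("%s.proj.W", pf)]]
  r <- cpp_block_fwd(x, kernels, gammas, betas, rmeans, rvars, projW,
                     residual, train, stride2, axis, 0.1, 1e-5)
  for (j in js) {
    state[[sprintf("%s.br%d.bn", pf, j)]] <-
      list(mean = r$rmeans[[j]], var = r$rvars[[j]])
  }
  list(y = r$y, state = state,
       cache = list(x = x, caches = r$caches, axis = axis,
                    residual = residual, stride2 = stride2, train = train,
                    pf = pf, nb = nb))
}

.block_backward <- function(dy, params, cache) {
  pf <- cache$pf
  js <- seq_len(cache$nb)
  kernels <- lapply(js, function(j) params[[sprintf("%s.br%d.W", pf, j)]])
  gammas <- lapply(js, function(j) params[[sprintf("%s.br%d.bn.g", pf, j)]])
  betas <- lapply(js, function(j) params[[sprintf("%s.br%d.bn.b", pf, j)]])
  projW <- params[[sprintf("%s.proj.W", pf)]]
  r <- cpp_block_bwd(dy, cache$x, kernels, gammas, betas, cache$caches,
                     projW,
                     cache$residual, cache$train, cache$stride2, cache$axis)
  grads <- list()
  for (j in js) {
    grads[[sprintf("%s.br%d.W", pf, j)]] <- r$dWs[[j]]
    grads[[sprintf("%s.br%d.bn.g", pf, j)]] <- r$dgs[[j]]
    grads[[sprintf("%s.br%d.bn.b", pf, j)]] <- r$dbs[[j]]
  }
  if (cache$residual && !is.null(projW)) {
    grads[[sprintf("%s.proj.W", pf)]] <- r$dprojW
  }
  list(dx = r$dx, grads = grads)
}

# ---------------------------------------------------------------------------
# Exported functional stage operations (evaluation-oriented surfaces; the
# training loop drives the cached internals directly).

#' Temporal stem convolution
#'
#' Applies the 1 x `stem_kernel` temporal convolution (stride 1, zero-padded
#' "same"), batch normalization and rectification to raw epochs arranged as a
#' one-channel feature map.
#'
#' @param x Array `[1, n_samples, n_channels, n_trials]` (or an
#'   `[n, ch, samples]` epoch array via [epochs_to_input()]).
#' @param model A [tspnet_init()] model.
#' @param train Use batch statistics (`TRUE`) or running statistics.
#' @return Feature array `[width, n_samples, n_channels, n_trials]`.
#' @export
stem_conv <- function(x, model, train = FALSE) {
  f <- .stem_forward(model$params, model$state, x, model$config, train)
  f$y
}

# The stem is a one-branch non-residual block: conv 1 x k, BN, ReLU.
.stem_forward <- function(params, state, x, config, train) {
  r <- cpp_block_fwd(x, list(params[["stem.W"]]),
                     list(params[["stem.bn.g"]]), list(params[["stem.bn.b"]]),
                     list(state[["stem.bn"]]$mean), list(state[["stem.bn"]]$var),
                     NULL, FALSE, train, FALSE, 2L, 0.1, 1e-5)
  state[["stem.bn"]] <- list(mean = r$rmeans[[1L]], var = r$rvars[[1L]])
  list(y = r$y, state = state,
       cache = list(x = x, caches = r$caches, train = train))
}

.stem_backward <- function(dy, params, cache) {
  r <- cpp_block_bwd(dy, cache$x, list(params[["stem.W"]]),
                     list(params[["stem.bn.g"]]), list(params[["stem.bn.b"]]),
                     cache$caches, NULL,
                     FALSE, cache$train, FALSE, 2L)
  list(dx = r$dx,
       grads = list("stem.W" = r$dWs[[1L]], "stem.bn.g" = r$dgs[[1L]],
                    "stem.bn.b" = r$dbs[[1L]]))
}

#' Standalone parallel residual block
#'
#' Functional form of the network's building block, for inspection and
#' testing: `sum_b relu(BN(conv(x, W_b) + skip(x)))` with `skip` the
#' identity when input and output widths match, a 1 x 1 projection
#' otherwise, and absent when `residual = FALSE`. Normalization sits after
#' the skip addition (see the methods vignette) and uses batch statistics.
#'
#' @param x Input array `[C_in, W, H, N]`.
#' @param weights List with `kernels` (list of `[C_out, C_in, k]` arrays),
#'   optional `gamma`/`beta` (lists of length-`C_out` vectors, default unit
#'   gain), and optional `proj` (`[C_out, C_in]` matrix, required when the
#'   widths differ and `residual = TRUE`).
#' @param axis `"temporal"` (1 x k kernels) or `"spatial"` (k x 1).
#' @param residual Include the additive skip.
#' @return Output array `[C_out, W, H, N]`.
#' @export
residual_parallel_block <- function(x, weights,
                                    axis = c("temporal", "spatial"),
                                    residual = TRUE) {
  axis <- match.arg(axis)
  ax <- if (axis == "temporal") 2L else 3L
  co <- dim(weights$kernels[[1L]])[1L]
  ci <- dim(x)[1L]
  params <- list()
  state <- list()
  for (j in seq_along(weights$kernels)) {
    k <- dim(weights$kernels[[j]])[3L]
    if (k %% 2L == 0L) stop("kernels must be odd-sized")
    params[[sprintf("blk.br%d.W", j)]] <- weights$kernels[[j]]
    params[[sprintf("blk.br%d.bn.g", j)]] <-
      if (is.null(weights$gamma)) rep(1, co) else weights$gamma[[j]]
    params[[sprintf("blk.br%d.bn.b", j)]] <-
      if (is.null(weights$beta)) rep(0, co) else weights$beta[[j]]
    state[[sprintf("blk.br%d.bn", j)]] <- list(mean = rep(0, co), var = rep(1, co))
  }
  if (residual && ci != co) {
    if (is.null(weights$proj)) {
      stop("width change with residual skip requires a projection matrix")
    }
    params[["blk.proj.W"]] <- weights$proj
  }
  .block_forward(params, state, "blk", x, ax, residual, train = TRUE)$y
}

#' Temporal feature-extraction stage
#'
#' Three successive parallel residual blocks convolving only along time,
#' widths increasing per the configuration. With `use_tdfe = FALSE` the
#' input passes through unchanged; with `tdfe_residual = FALSE` the blocks
#' drop their skip connections.
#'
#' @param x Post-stem feature array.
#' @inheritParams stem_conv
#' @return Feature array with the final stage width.
#' @export
tdfe_forward <- function(x, model, train = FALSE) {
  .tdfe_forward(model$params, model$state, x, model$config, train)$y
}

.tdfe_forward <- function(params, state, x, config, train) {
  if (!config$use_tdfe) {
    return(list(y = x, state = state, cache = list(skipped = TRUE)))
  }
  caches <- vector("list", 3L)
  for (i in 1:3) {
    f <- .block_forward(params, state, sprintf("tdfe%d", i), x, axis = 2L,
                        residual = config$tdfe_residual, train = train)
    x <- f$y; state <- f$state; caches[[i]] <- f$cache
  }
  list(y = x, state = state, cache = list(skipped = FALSE, blocks = caches))
}

.tdfe_backward <- function(dy, params, cache) {
  if (isTRUE(cache$skipped)) return(list(dx = dy, grads = list()))
  grads <- list()
  for (i in 3:1) {
    b <- .block_backward(dy, params, cache$blocks[[i]])
    dy <- b$dx
    grads <- c(grads, b$grads)
  }
  list(dx = dy, grads = grads)
}

#' Spatial feature-extraction stage
#'
#' One parallel residual block convolving only across electrodes (kernels
#' 1 x 1, 3 x 1, 5 x 1 summed elementwise), followed by spatial reduction:
#' max-pooling of size 2 / stride 2 (default) or stride-2 convolution (the
#' no-pooling variant). With `use_sdfe = FALSE` the input passes through.
#'
#' @param x Post-TDFE feature array.
#' @inheritParams stem_conv
#' @return Feature array with halved spatial extent (when active).
#' @export
sdfe_forward <- function(x, model, train = FALSE) {
  .sdfe_forward(model$params, model$state, x, model$config, train)$y
}

.sdfe_forward <- function(params, state, x, config, train) {
  if (!config$use_sdfe) {
    return(list(y = x, state = state, cache = list(skipped = TRUE)))
  }
  if (dim(x)[3L] < 2L) stop("spatial extent < 2: cannot reduce spatially")
  stride2 <- config$sdfe_pooling_mode == "stride2"
  f <- .block_forward(params, state, "sdfe", x, axis = 3L, residual = TRUE,
                      train = train, stride2 = stride2)
  state <- f$state
  if (stride2) {
    return(list(y = f$y, state = state,
                cache = list(skipped = FALSE, block = f$cache, pool = NULL)))
  }
  p <- maxpool_h_forward(f$y)
  list(y = p$y, state = state,
       cache = list(skipped = FALSE, block = f$cache, pool = p$cache))
}

.sdfe_backward <- function(dy, params, cache) {
  if (isTRUE(cache$skipped)) return(list(dx = dy, grads = list()))
  if (!is.null(cache$pool)) dy <- maxpool_h_backward(dy, cache$pool)
  .block_backward(dy, params, cache$block)
}

#' Temporal decimation
#'
#' Average pooling along the temporal axis with window = stride = the
#' smallest integer bringing the extent to at most `w_max`; identity when
#' already within the cap. Keeps the similarity matrices of the time-spatial
#' head at a tractable size.
#'
#' @param x Feature array `[C, W, H, N]`.
#' @param w_max Maximum temporal extent.
#' @return Feature array `[C, W', H, N]` with `W' <= w_max`.
#' @export
temporal_decimate <- function(x, w_max) {
  temporal_decimate_forward(x, w_max)$y
}

#' Arrange an epoch set as network input
#'
#' @param epochs An [epoch_set()] or an `[n, channels, samples]` array.
#' @return Array `[1, n_samples, n_channels, n_trials]`.
#' @export
epochs_to_input <- function(epochs) {
  a <- if (inherits(epochs, "epoch_set")) epochs$data else epochs
  d <- dim(a)
  x <- aperm(a, c(3L, 2L, 1L))  # samples, channels, trials
  dim(x) <- c(1L, d[3L], d[2L], d[1L])
  x
}
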