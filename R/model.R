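# Full network: stem -> TDFE -> SDFE -> temporal decimation -> TSPFE ->
# GAP/affine/softmax head, with cached forward and exact backward for
# training.

# Forward pass over a batch.
# x: [1, W, H, N] input; returns probs [K, N], per-stage caches, updated
# batch-norm state, and the requested tap activations.
tspnet_forward <- function(params, state, x, config, train = FALSE,
                           tap = NULL) {
  f_stem <- .stem_forward(params, state, x, config, train)
  state <- f_stem$state
  f_tdfe <- .tdfe_forward(params, state, f_stem$y, config, train)
  state <- f_tdfe$state
  f_sdfe <- .sdfe_forward(params, state, f_tdfe$y, config, train)
  state <- f_sdfe$state
  f_dec <- temporal_decimate_forward(f_sdfe$y, config$w_max)
  f_tspfe <- .tspfe_forward(params, f_dec$y, config, train)
  f_head <- .head_forward(params, f_tspfe$y)
  taps <- list()
  if (!is.null(tap)) {
    taps <- list(
      post_stem = if ("post_stem" %in% tap) f_stem$y,
      post_tdfe = if ("post_tdfe" %in% tap) f_tdfe$y,
      post_sdfe = if ("post_sdfe" %in% tap) f_sdfe$y,
      pre_tspfe = if ("pre_tspfe" %in% tap) f_dec$y,
      tspfe = if ("tspfe" %in% tap) f_tspfe$y
    )
  }
  list(probs = f_head$probs, logits = f_head$logits, state = state,
       taps = taps,
       caches = list(stem = f_stem$cache, tdfe = f_tdfe$cache,
                     sdfe = f_sdfe$cache, dec = f_dec$cache,
                     tspfe = f_tspfe$cache, head = f_head$cache))
}

# Backward pass from the logit gradient; returns the flat gradient list
# (same names as params).
tspnet_backward <- function(params, caches, dlogits, config) {
  b_head <- .head_backward(dlogits, params, caches$head)
  b_tspfe <- .tspfe_backward(b_head$dx, params, caches$tspfe)
  d_dec <- temporal_decimate_backward(b_tspfe$dx, caches$dec)
  b_sdfe <- .sdfe_backward(d_dec, params, caches$sdfe)
  b_tdfe <- .tdfe_backward(b_sdfe$dx, params, caches$tdfe)
  b_stem <- .stem_backward(b_tdfe$dx, params, caches$stem)
  grads <- c(b_head$grads, b_tspfe$grads, b_sdfe$grads, b_tdfe$grads,
             b_stem$grads)
  # align with parameter order; absent entries (unused stages) are zeros
  out <- params
  for (nm in names(out)) {
    g <- grads[[nm]]
    if (is.null(g)) {
      out[[nm]][] <- 0
    } else {
      gv <- out[[nm]]
      gv[] <- as.numeric(g)
      out[[nm]] <- gv
    }
  }
  out
}

# Loss + gradients for one labeled batch (training mode).
tspnet_loss_grad <- function(model, x, labels, class_weights = NULL) {
  fwd <- tspnet_forward(model$params, model$state, x, model$config,
                        train = TRUE)
  loss <- cross_entropy_loss(fwd$probs, labels, class_weights)
  dlogits <- .ce_logit_grad(fwd$probs, labels, class_weights)
  grads <- tspnet_backward(model$params, fwd$caches, dlogits, model$config)
  list(loss = loss, grads = grads, state = fwd$state, probs = fwd$probs)
}

#' Class probabilities for an epoch set
#'
#' Runs the network in evaluation mode (batch-norm running statistics;
#' bit-reproducible for identical weights and input).
#'
#' @param model A trained (or initialized) `tspnet_model`.
#' @param epochs An [epoch_set()] or `[n, channels, samples]` array; trials
#'   are processed in chunks to bound memory.
#' @param chunk Trials per forward chunk.
#' @return Matrix `[n_trials, n_classes]` of class probabilities.
#' @export
predict_proba <- function(model, epochs, chunk = 64L) {
  x_all <- epochs_to_input(epochs)
  n <- dim(x_all)[4L]
  out <- matrix(0, n, model$config$n_classes)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fwd <- tspnet_forward(model$params, model$state,
                          x_all[, , , idx, drop = FALSE],
                          model$config, train = FALSE)
    out[idx, ] <- t(fwd$probs)
  }
  out
}

#' Predicted class labels
#'
#' Argmax over [predict_proba()]; ties break toward the lowest class index.
#'
#' @inheritParams predict_proba
#' @return Integer vector of class indices `0..K-1`.
#' @export
predict_classes <- function(model, epochs, chunk = 64L) {
  p <- predict_proba(model, epochs, chunk)
  max.col(p, ties.method = "first") - 1L
}

#' Extract intermediate feature maps
#'
#' Runs the forward pass in evaluation mode up to a tap point and returns
#' the activations: `"tspfe"` (default; the concatenated gated output of the
#' time-spatial head) or `"pre_tspfe"` (after spatial reduction and temporal
#' decimation, before the head) — the two taps compared by the
#' before/after-head visualization — plus earlier stages.
#'
#' @inheritParams predict_proba
#' @param tap One of `"tspfe"`, `"pre_tspfe"`, `"post_sdfe"`,
#'   `"post_tdfe"`, `"post_stem"`.
#' @return Feature array `[C, W, H, n_trials]`.
#' @export
extract_features <- function(model, epochs, tap = "tspfe", chunk = 64L) {
  tap <- match.arg(tap, c("tspfe", "pre_tspfe", "post_sdfe", "post_tdfe",
                          "post_stem"))
  x_all <- epochs_to_input(epochs)
  n <- dim(x_all)[4L]
  pieces <- list()
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fwd <- tspnet_forward(model$params, model$state,
                          x_all[, , , idx, drop = FALSE],
                          model$config, train = FALSE, tap = tap)
    pieces[[length(pieces) + 1L]] <- fwd$taps[[tap]]
  }
  d1 <- dim(pieces[[1L]])
  out <- array(0, c(d1[1L], d1[2L], d1[3L], n))
  at <- 0L
  for (p in pieces) {
    k <- dim(p)[4L]
    out[, , , at + seq_len(k)] <- p
    at <- at + k
  }
  out
}

# Finite-difference gradient check used by the test suite: compares the
# analytic gradient of the scalar loss with central differences for a random
# subset of coordinates of every parameter.
numeric_grad_check <- function(model, x, labels, n_coords = 3L, eps = 1e-5,
                               seed = 1L) {
  an <- tspnet_loss_grad(model, x, labels)
  worst <- 0
  with_seed(seed, {
    for (nm in names(model$params)) {
      npar <- length(model$params[[nm]])
      coords <- sample.int(npar, min(n_coords, npar))
      for (ci in coords) {
        m2 <- model
        m2$params[[nm]][ci] <- m2$params[[nm]][ci] + eps
        lp <- tspnet_loss_grad(m2, x, labels)$loss
        m2$params[[nm]][ci] <- m2$params[[nm]][ci] - 2 * eps
        lm <- tspnet_loss_grad(m2, x, labels)$loss
        num <- (lp - lm) / (2 * eps)
        ana <- an$grads[[nm]][ci]
        err <- abs(num - ana) / max(1, abs(num), abs(ana))
        worst <- max(worst, err)
      }
    }
  })
  worst
}
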