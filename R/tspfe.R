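# Time-spatial parallel feature extractor: per feature channel, a W x W
# similarity matrix Q = (PX)' D (PX) is built from the H x W channel slice X
# with a shared orthogonal P (matrix exponential of a skew-symmetric
# generator) and learnable diagonal D; Q is softmax-normalized down columns
# and down columns of its transpose, each normalization re-projects X, and a
# rectified gate reweights each branch before concatenation.

#' Orthogonal matrix from an unconstrained generator
#'
#' `P = expm(A - t(A))`: the matrix exponential of the skew-symmetric part
#' of `A` is exactly orthogonal, so orthogonality holds by construction for
#' any parameter value and is preserved under gradient updates of `A`.
#'
#' @param A Square numeric matrix.
#' @return Orthogonal matrix `P` of the same size.
#' @export
#' @examples
#' P <- orthogonalize(matrix(rnorm(9), 3))
#' max(abs(crossprod(P) - diag(3))) < 1e-5
orthogonalize <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("A must be a square matrix")
  S <- A - t(A)
  as.matrix(Matrix::expm(Matrix::Matrix(S)))
}

# Adjoint of the Frechet derivative of the matrix exponential at the
# skew-symmetric point S: given G = dL/dP, returns dL/dS via the block
# identity expm([[S', G], [0, S']]) whose top-right block is the derivative
# of expm at S' in direction G.
.expm_frechet_adjoint <- function(S, G) {
  h <- nrow(S)
  blk <- rbind(cbind(t(S), G), cbind(matrix(0, h, h), t(S)))
  E <- as.matrix(Matrix::expm(Matrix::Matrix(blk)))
  E[seq_len(h), h + seq_len(h), drop = FALSE]
}

#' Similarity matrix of one channel slice
#'
#' `Q = (P X)' D (P X)` for a channel slice `X` of shape `[H, W]`; entries
#' of `Q` measure similarity between temporal positions after the orthogonal
#' spatial projection. `P` and `D` are shared across feature channels.
#'
#' @param X Numeric matrix `[H, W]`.
#' @param A Generator of the orthogonal projection (see [orthogonalize()]).
#' @param d Diagonal entries of `D`, length `H`.
#' @return Numeric matrix `[W, W]`.
#' @export
similarity_matrix <- function(X, A, d) {
  if (nrow(X) != nrow(A) || length(d) != nrow(A)) {
    stop("H mismatch between X and the (P, D) parameters")
  }
  P <- orthogonalize(A)
  PX <- P %*% X
  crossprod(PX, d * PX)
}

#' Column- and row-normalization of a similarity matrix
#'
#' `Qc` is the column-wise softmax of `Q`; `Qr` is the column-wise softmax
#' of `t(Q)` (equivalently a row-normalization of `Q`). Every column of each
#' result sums to one.
#'
#' @param Q Square numeric matrix.
#' @return List with `Qc` and `Qr`.
#' @export
normalize_similarity <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("Q must be square")
  list(Qc = softmax_cols(Q), Qr = softmax_cols(t(Q)))
}

#' Project a channel slice through normalized similarities
#'
#' `Fc = X Qc` and `Fr = X Qr`, per feature channel.
#'
#' @param X Numeric matrix `[H, W]`.
#' @param Qc,Qr Normalized similarity matrices `[W, W]`.
#' @return List with `Fc` and `Fr`.
#' @export
parallel_project <- function(X, Qc, Qr) {
  if (ncol(X) != nrow(Qc) || ncol(X) != nrow(Qr)) {
    stop("temporal extents of X and Q do not conform")
  }
  list(Fc = X %*% Qc, Fr = X %*% Qr)
}

#' Rectified gating of a projected feature
#'
#' `F' = F * relu(w_f . F + b_f)` elementwise, where `w_f . F` is a 1 x 1
#' convolution across feature channels producing one gate value per
#' position, broadcast back over channels. The rectifier is the stated
#' activation of the gating mechanism.
#'
#' @param F Feature array `[C, W, H, N]` (or a matrix `[C, positions]`).
#' @param w Gate weights, length `C`.
#' @param b Gate bias (scalar).
#' @return Gated feature of the same shape.
#' @export
gated_features <- function(F, w, b) {
  d <- dim(F)
  Fm <- if (length(d) > 2L) .as_cwhn_matrix(F) else as.matrix(F)
  u <- as.numeric(crossprod(Fm, w)) + b
  g <- pmax(u, 0)
  out <- Fm * rep(g, each = nrow(Fm))
  dim(out) <- d
  out
}

# Full TSPFE forward over a batch. x: [C, W, H, N]. Shared (P, D), separate
# gates for the column and row branches; output concatenates the two gated
# branches along the channel axis.
.tspfe_forward <- function(params, x, config, train) {
  if (!config$use_tspfe) {
    return(list(y = x, cache = list(skipped = TRUE)))
  }
  d <- dim(x)
  C <- d[1L]; W <- d[2L]; H <- d[3L]; N <- d[4L]
  A <- params[["tspfe.A"]]
  dd <- params[["tspfe.d"]]
  P <- orthogonalize(A)
  M <- crossprod(P, dd * P)  # symmetric H x H
  xp <- aperm(x, c(3L, 2L, 1L, 4L))  # [H, W, C, N]
  dim(xp) <- c(H, W, C * N)
  sim <- cpp_tspfe_fwd(xp, M)
  Sc <- sim$Sc
  Sr <- sim$Sr
  # back to [C, W, H, N] for the gates
  Fc <- aperm(array(sim$Fc, c(H, W, C, N)), c(3L, 2L, 1L, 4L))
  Fr <- aperm(array(sim$Fr, c(H, W, C, N)), c(3L, 2L, 1L, 4L))
  Fcm <- .as_cwhn_matrix(Fc)
  Frm <- .as_cwhn_matrix(Fr)
  uc <- as.numeric(crossprod(Fcm, params[["tspfe.gc.w"]])) + params[["tspfe.gc.b"]]
  ur <- as.numeric(crossprod(Frm, params[["tspfe.gr.w"]])) + params[["tspfe.gr.b"]]
  gc <- pmax(uc, 0)
  gr <- pmax(ur, 0)
  Fcg <- Fcm * rep(gc, each = C)
  Frg <- Frm * rep(gr, each = C)
  y <- array(0, c(2L * C, W, H, N))
  y[seq_len(C), , , ] <- array(Fcg, c(C, W, H, N))
  y[C + seq_len(C), , , ] <- array(Frg, c(C, W, H, N))
  list(y = y, cache = list(
    skipped = FALSE, xp = xp, P = P, M = M, dd = dd,
    Sc = Sc, Sr = Sr, Fcm = Fcm, Frm = Frm,
    gc = gc, gr = gr, uc = uc, ur = ur, dims = d
  ))
}

.tspfe_backward <- function(dy, params, cache) {
  if (isTRUE(cache$skipped)) return(list(dx = dy, grads = list()))
  d <- cache$dims
  C <- d[1L]; W <- d[2L]; H <- d[3L]; N <- d[4L]
  dyc <- dy[seq_len(C), , , , drop = FALSE]
  dyr <- dy[C + seq_len(C), , , , drop = FALSE]
  dycm <- .as_cwhn_matrix(dyc)
  dyrm <- .as_cwhn_matrix(dyr)

  # gate backward (vectorized over all positions)
  wc <- params[["tspfe.gc.w"]]; wr <- params[["tspfe.gr.w"]]
  duc <- colSums(dycm * cache$Fcm) * (cache$uc > 0)
  dur <- colSums(dyrm * cache$Frm) * (cache$ur > 0)
  gwc <- as.numeric(cache$Fcm %*% duc)
  gwr <- as.numeric(cache$Frm %*% dur)
  gbc <- sum(duc)
  gbr <- sum(dur)
  dFcm <- dycm * rep(cache$gc, each = C) + outer(wc, duc)
  dFrm <- dyrm * rep(cache$gr, each = C) + outer(wr, dur)
  dFc <- aperm(array(dFcm, c(C, W, H, N)), c(3L, 2L, 1L, 4L))  # [H, W, C, N]
  dFr <- aperm(array(dFrm, c(C, W, H, N)), c(3L, 2L, 1L, 4L))
  dim(dFc) <- c(H, W, C * N)
  dim(dFr) <- c(H, W, C * N)
  sim <- cpp_tspfe_bwd(cache$xp, cache$M, cache$Sc, cache$Sr, dFc, dFr)
  dxp <- array(sim$dxp, c(H, W, C, N))
  dM <- sim$dM
  P <- cache$P
  G <- dM
  Gs <- G + t(G)
  dP <- cache$dd * (P %*% Gs)        # diag(d) P (G + G')
  dd_grad <- diag(P %*% G %*% t(P))
  S <- params[["tspfe.A"]] - t(params[["tspfe.A"]])
  dSkew <- .expm_frechet_adjoint(S, dP)
  dA <- dSkew - t(dSkew)
  dx <- aperm(dxp, c(3L, 2L, 1L, 4L))
  list(dx = dx, grads = list(
    "tspfe.A" = dA, "tspfe.d" = dd_grad,
    "tspfe.gc.w" = gwc, "tspfe.gc.b" = gbc,
    "tspfe.gr.w" = gwr, "tspfe.gr.b" = gbr
  ))
}

# ---------------------------------------------------------------------------
# Head: global average pooling over (W, H), affine map, softmax.

.head_forward <- function(params, x) {
  d <- dim(x)
  C <- d[1L]; N <- d[4L]
  z <- matrix(0, C, N)
  xm <- array(x, c(C, d[2L] * d[3L], N))
  for (n in seq_len(N)) z[, n] <- rowMeans(xm[, , n, drop = FALSE])
  logits <- params[["head.W"]] %*% z + params[["head.b"]]
  probs <- softmax_cols(logits)
  list(probs = probs, logits = logits,
       cache = list(z = z, d = d, probs = probs))
}

.head_backward <- function(dlogits, params, cache) {
  d <- cache$d
  dW <- dlogits %*% t(cache$z)
  db <- rowSums(dlogits)
  dz <- crossprod(params[["head.W"]], dlogits)  # [C, N]
  wh <- d[2L] * d[3L]
  dzs <- dz / wh
  # broadcast dz/(W*H) over every (w, h) position
  dx <- array(0, d)
  for (n in seq_len(d[4L])) dx[, , , n] <- dzs[, n]
  list(dx = dx, grads = list("head.W" = dW, "head.b" = db))
}

#' Classifier head: global average pooling, affine map, softmax
#'
#' @param x Feature array `[C, W, H, N]`.
#' @param model A [tspnet_init()] model.
#' @return Probability matrix `[n_classes, N]`; every column sums to one.
#' @export
classifier_head <- function(x, model) {
  .head_forward(model$params, x)$probs
}

#' Weighted multiclass cross-entropy
#'
#' `loss = -(1/N) sum_n sum_i w_i t_ni log y_ni` with one-hot targets,
#' averaged over trials. Probabilities at the true class are clamped at
#' `1e-12` with a warning if they underflow to zero.
#'
#' @param probs Probability matrix, trials in columns (`[K, N]`) or rows
#'   (`[N, K]`); each trial's probabilities must sum to one.
#' @param labels Integer class labels `0..K-1`, length `N`.
#' @param class_weights Positive per-class weights (default all one).
#' @return Non-negative scalar loss.
#' @export
#' @examples
#' p <- matrix(1 / 6, 6, 10)
#' cross_entropy_loss(p, rep(0:5, 2)[1:10])  # log(6)
cross_entropy_loss <- function(probs, labels, class_weights = NULL) {
  if (!is.matrix(probs)) stop("probs must be a matrix")
  if (ncol(probs) == length(labels)) {
    # columns are trials
  } else if (nrow(probs) == length(labels)) {
    probs <- t(probs)
  } else {
    stop("probs dimensions do not match labels")
  }
  K <- nrow(probs)
  N <- ncol(probs)
  if (any(abs(colSums(probs) - 1) > 1e-6)) {
    stop("each trial's probabilities must sum to 1")
  }
  if (is.null(class_weights)) class_weights <- rep(1, K)
  if (any(class_weights <= 0)) stop("class weights must be positive")
  idx <- cbind(labels + 1L, seq_len(N))
  p_true <- probs[idx]
  if (any(p_true <= 0)) {
    warning("zero probability at the true class; clamping at 1e-12")
    p_true <- pmax(p_true, 1e-12)
  }
  -mean(class_weights[labels + 1L] * log(p_true))
}

# Gradient of the mean weighted cross-entropy with respect to the logits
# (softmax and loss fused).
.ce_logit_grad <- function(probs, labels, class_weights = NULL) {
  K <- nrow(probs); N <- ncol(probs)
  if (is.null(class_weights)) class_weights <- rep(1, K)
  t1 <- matrix(0, K, N)
  t1[cbind(labels + 1L, seq_len(N))] <- 1
  w <- class_weights[labels + 1L]
  sweep(probs - t1, 2L, w, "*") / N
}
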