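test_that("orthogonalization is exact by construction", {
  expect_equal(orthogonalize(matrix(0, 3, 3)), diag(3))
  set.seed(50)
  for (i in 1:5) {
    h <- sample(2:6, 1L)
    P <- orthogonalize(matrix(rnorm(h * h), h))
    expect_lt(max(abs(crossprod(P) - diag(h))), 1e-5)
  }
  # 2-d closed form: skew part [[0, theta], [-theta, 0]] rotates by theta
  th <- pi / 2
  A <- matrix(c(0, -th / 2, th / 2, 0), 2, 2)  # A - t(A) = [[0, th], [-th, 0]]
  P <- orthogonalize(A)
  expect_equal(P, matrix(c(0, -1, 1, 0), 2, 2), tolerance = 1e-8)
  expect_error(orthogonalize(matrix(0, 2, 3)), "square")
})

test_that("similarity matrix matches a loop-based triple-product oracle", {
  set.seed(51)
  for (i in 1:8) {
    h <- sample(2:4, 1L); w <- sample(3:5, 1L)
    X <- matrix(rnorm(h * w), h)
    A <- matrix(rnorm(h * h), h)
    d <- runif(h, 0.5, 2)
    got <- similarity_matrix(X, A, d)
    P <- orthogonalize(A)
    PX <- P %*% X
    want <- matrix(0, w, w)
    for (a in seq_len(w)) for (b in seq_len(w)) {
      want[a, b] <- sum(PX[, a] * d * PX[, b])
    }
    expect_equal(got, want, tolerance = 1e-6)
  }
  # identity projection and unit diagonal give the Gram matrix
  X <- matrix(rnorm(12), 3)
  Q <- similarity_matrix(X, matrix(0, 3, 3), rep(1, 3))
  expect_equal(Q, crossprod(X), tolerance = 1e-8)
  expect_true(isSymmetric(Q, tol = 1e-8))
  expect_true(all(eigen(Q, only.values = TRUE)$values > -1e-8))
  # orthogonal columns give a diagonal Gram matrix
  Xo <- qr.Q(qr(matrix(rnorm(9), 3)))
  Qo <- similarity_matrix(Xo, matrix(0, 3, 3), rep(1, 3))
  expect_equal(Qo, diag(3), tolerance = 1e-8)
})

test_that("similarity normalization produces column-stochastic matrices", {
  set.seed(52)
  Q <- matrix(rnorm(25), 5)
  ns <- normalize_similarity(Q)
  expect_equal(unname(colSums(ns$Qc)), rep(1, 5), tolerance = 1e-6)
  expect_equal(unname(colSums(ns$Qr)), rep(1, 5), tolerance = 1e-6)
  # zero matrix -> uniform weights
  u <- normalize_similarity(matrix(0, 4, 4))
  expect_equal(u$Qc, matrix(1 / 4, 4, 4))
  # hand-evaluated 2x2 case
  Q2 <- matrix(c(0, 0, log(3), 0), 2, 2)
  expect_equal(normalize_similarity(Q2)$Qc[, 2L], c(3 / 4, 1 / 4),
               tolerance = 1e-10)
  # transposing Q swaps the roles of the two normalizations
  ns2 <- normalize_similarity(t(Q))
  expect_equal(ns2$Qc, ns$Qr)
  expect_equal(ns2$Qr, ns$Qc)
})

test_that("parallel projection matches a loop-based product and its special cases", {
  set.seed(53)
  X <- matrix(rnorm(12), 3)  # 3 x 4
  Q <- matrix(runif(16), 4)
  Qc <- sweep(Q, 2L, colSums(Q), "/")
  pp <- parallel_project(X, Qc, Qc)
  want <- matrix(0, 3, 4)
  for (i in 1:3) for (j in 1:4) want[i, j] <- sum(X[i, ] * Qc[, j])
  expect_equal(pp$Fc, want, tolerance = 1e-6)
  # identity leaves X unchanged; uniform averaging gives row means
  expect_equal(parallel_project(X, diag(4), diag(4))$Fc, X)
  U <- matrix(1 / 4, 4, 4)
  Fu <- parallel_project(X, U, U)$Fc
  expect_equal(Fu, matrix(rowMeans(X), 3, 4), tolerance = 1e-8)
  expect_error(parallel_project(X, diag(3), diag(4)), "conform")
})

test_that("the rectified gate behaves per its closed forms", {
  F <- array(rnorm(3 * 2 * 2 * 2), c(3L, 2L, 2L, 2L))
  # closed gate: zero weights, negative bias
  expect_true(all(gated_features(F, rep(0, 3), -1) == 0))
  # unit gate: zero weights, bias one
  expect_equal(gated_features(F, rep(0, 3), 1), F)
  # scalar case: F = 2, w = 1, b = 0 -> 2 * relu(2) = 4
  Fs <- array(2, c(1L, 1L, 1L, 1L))
  expect_equal(as.numeric(gated_features(Fs, 1, 0)), 4)
})

test_that("the head concatenates both branches and a disabled head passes through", {
  cfg <- tiny_model_config()
  m <- tspnet_init(cfg)
  set.seed(54)
  x <- array(rnorm(5 * 6 * 2 * 3), c(5L, 6L, 2L, 3L))
  out <- tspnet:::.tspfe_forward(m$params, x, cfg, train = TRUE)
  expect_equal(dim(out$y), c(10L, 6L, 2L, 3L))
  cfg2 <- tiny_model_config(use_tspfe = FALSE)
  m2 <- tspnet_init(cfg2)
  out2 <- tspnet:::.tspfe_forward(m2$params, x, cfg2, train = TRUE)
  expect_identical(out2$y, x)
  # all-zero input with non-positive gate bias stays zero
  p0 <- m$params
  p0[["tspfe.gc.b"]] <- 0
  p0[["tspfe.gr.b"]] <- 0
  z <- array(0, dim(x))
  expect_true(all(tspnet:::.tspfe_forward(p0, z, cfg, TRUE)$y == 0))
})

test_that("classifier head produces normalized probabilities with expected special cases", {
  cfg <- tiny_model_config()
  m <- tspnet_init(cfg)
  set.seed(55)
  x <- array(rnorm(10 * 6 * 2 * 4), c(10L, 6L, 2L, 4L))
  p <- classifier_head(x, m)
  expect_equal(unname(colSums(p)), rep(1, 4), tolerance = 1e-6)
  expect_true(all(p > 0 & p < 1))
  # zero weights and bias -> uniform prediction
  m0 <- m
  m0$params[["head.W"]][] <- 0
  m0$params[["head.b"]][] <- 0
  expect_equal(classifier_head(x, m0), matrix(1 / 6, 6, 4), tolerance = 1e-10)
  # constant feature map -> GAP equals the constant on every channel
  xc <- array(2.5, c(10L, 6L, 2L, 1L))
  expect_equal(tspnet:::.head_forward(m$params, xc)$cache$z,
               matrix(2.5, 10L, 1L))
})

test_that("cross-entropy has its analytic values and scales linearly in the weights", {
  # uniform predictions: loss = log(6)
  p <- matrix(1 / 6, 6, 12)
  labs <- rep(0:5, 2)
  expect_equal(cross_entropy_loss(p, labs), log(6), tolerance = 1e-12)
  # perfect one-hot predictions: zero loss (clamped-probability warning-free)
  ph <- matrix(1e-12, 6, 6)
  ph[cbind(1:6, 1:6)] <- 1 - 5e-12
  ph <- sweep(ph, 2L, colSums(ph), "/")
  expect_lt(cross_entropy_loss(ph, 0:5), 1e-9)
  # doubling the class weights doubles the loss
  set.seed(56)
  q <- matrix(runif(6 * 8), 6)
  q <- sweep(q, 2L, colSums(q), "/")
  l1 <- cross_entropy_loss(q, sample(0:5, 8, TRUE), rep(1, 6))
  l2 <- cross_entropy_loss(q, sample(0:5, 8, TRUE), rep(2, 6))
  l1b <- cross_entropy_loss(q, rep(0:3, 2), rep(1, 6))
  expect_equal(cross_entropy_loss(q, rep(0:3, 2), rep(2, 6)), 2 * l1b)
  expect_error(cross_entropy_loss(q * 2, rep(0, 8)), "sum to 1")
})

test_that("analytic gradients match central differences on a tiny network", {
  cfg <- tiny_model_config()
  m <- tspnet_init(cfg)
  set.seed(57)
  x <- array(rnorm(1 * 12 * 4 * 3), c(1L, 12L, 4L, 3L))
  err <- tspnet:::numeric_grad_check(m, x, c(0L, 3L, 5L), n_coords = 3L)
  expect_lt(err, 1e-4)
})

test_that("evaluation-mode forward passes are bit-reproducible", {
  cfg <- tiny_model_config()
  m <- tspnet_init(cfg)
  es <- tiny_epochs()
  p1 <- predict_proba(m, es)
  p2 <- predict_proba(m, es)
  expect_identical(p1, p2)
})
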