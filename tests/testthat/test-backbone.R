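test_that("configuration validation enforces the architectural invariants", {
  expect_error(tspnet_config(tdfe_widths = c(64L, 64L, 128L)), "increasing")
  expect_error(tspnet_config(stem_kernel = 6L), "odd")
  expect_error(tspnet_config(w_max = 2L), "w_max")
  cfg <- tspnet_config()
  expect_equal(cfg$tdfe_widths, c(64L, 128L, 256L))
  expect_equal(cfg$sdfe_kernels, c(1L, 3L, 5L))
})

test_that("stem maps one input channel to the first stage width at unchanged extents", {
  cfg <- tspnet_config(n_input_channels = 16L, n_samples = 1500L)
  m <- tspnet_init(cfg)
  x <- array(rnorm(16 * 1500), c(1L, 1500L, 16L, 1L))
  y <- stem_conv(x, m, train = TRUE)
  expect_equal(dim(y), c(64L, 1500L, 16L, 1L))
})

test_that("an impulse through the stem convolution has support at most the kernel width", {
  w <- array(rnorm(3 * 1 * 7), c(3L, 1L, 7L))
  x <- array(0, c(1L, 41L, 2L, 1L))
  x[1L, 21L, 1L, 1L] <- 1
  y <- conv_axis_forward(x, w, axis = 2L)
  support <- which(apply(abs(y) > 0, 2L, any))
  expect_lte(diff(range(support)) + 1L, 7L)
  expect_true(all(y[, , 2L, ] == 0))  # temporal kernel does not mix electrodes
})

test_that("parallel residual block matches a straight-line oracle", {
  set.seed(40)
  for (draw in 1:6) {
    x <- array(rnorm(4 * 6 * 3 * 2), c(4L, 6L, 3L, 2L))
    # equal widths (identity skip) and width change (projection skip)
    for (co in c(4L, 5L)) {
      wts <- random_block_weights(4L, co, c(1L, 3L), seed = 100 + draw * 10 + co)
      got <- residual_parallel_block(x, wts, axis = "temporal", residual = TRUE)
      want <- naive_block(x, wts, axis = 2L, residual = TRUE)
      expect_equal(got, want, tolerance = 1e-5)
      got_nr <- residual_parallel_block(x, wts, axis = "temporal", residual = FALSE)
      want_nr <- naive_block(x, wts, axis = 2L, residual = FALSE)
      expect_equal(got_nr, want_nr, tolerance = 1e-5)
    }
    # spatial-axis variant
    wts <- random_block_weights(4L, 4L, c(1L, 3L, 5L), seed = 200 + draw)
    got <- residual_parallel_block(x, wts, axis = "spatial")
    want <- naive_block(x, wts, axis = 3L, residual = TRUE)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("zeroed branches reduce the block to its skip behavior", {
  set.seed(41)
  x <- array(rnorm(3 * 5 * 4 * 2), c(3L, 5L, 4L, 2L))
  zero_wts <- list(kernels = list(array(0, c(3L, 3L, 1L)), array(0, c(3L, 3L, 3L))))
  # with residual: each branch contributes relu(BN(0 + x)) -> 2 * relu(BN(x))
  got <- residual_parallel_block(x, zero_wts, axis = "temporal", residual = TRUE)
  want <- 2 * pmax(naive_bn(x, rep(1, 3), rep(0, 3)), 0)
  expect_equal(got, want, tolerance = 1e-6)
  # without residual: BN of an all-zero map is zero, so the output is zero
  got_nr <- residual_parallel_block(x, zero_wts, axis = "temporal", residual = FALSE)
  expect_true(all(got_nr == 0))
})

test_that("stage stacking follows the width/extent contract for random configs", {
  set.seed(42)
  for (i in 1:4) {
    nch <- sample(c(6L, 8L, 16L), 1L)
    ns <- sample(c(20L, 36L), 1L)
    widths <- cumsum(sample(2:4, 3L, replace = TRUE))
    cfg <- tspnet_config(n_input_channels = nch, n_samples = ns,
                         tdfe_widths = widths, sdfe_width = max(widths) + 2L,
                         w_max = 8L, seed = i)
    m <- tspnet_init(cfg)
    x <- epochs_to_input(array(rnorm(2 * nch * ns), c(2L, nch, ns)))
    fwd <- tspnet_forward(m$params, m$state, x, cfg, train = TRUE,
                          tap = c("post_tdfe", "post_sdfe", "pre_tspfe", "tspfe"))
    sh <- tspnet_shapes(cfg)
    expect_equal(dim(fwd$taps$post_tdfe)[1:3], sh$tdfe)
    expect_equal(dim(fwd$taps$post_sdfe)[1:3], sh$sdfe)
    expect_equal(dim(fwd$taps$pre_tspfe)[1:3], sh$decimate)
    expect_equal(dim(fwd$taps$tspfe)[1:3], sh$tspfe)
    expect_lte(dim(fwd$taps$pre_tspfe)[2L], cfg$w_max)
    expect_equal(dim(fwd$taps$post_sdfe)[3L], nch %/% 2L)
    expect_true(all(is.finite(fwd$taps$tspfe)))
  }
})

test_that("temporal stage is equivariant to electrode permutations", {
  cfg <- tiny_model_config()
  m <- tspnet_init(cfg)
  set.seed(43)
  x <- array(rnorm(1 * 12 * 4 * 2), c(1L, 12L, 4L, 2L))
  perm <- c(3L, 1L, 4L, 2L)
  f1 <- tspnet:::.stem_forward(m$params, m$state, x, cfg, TRUE)
  t1 <- tspnet:::.tdfe_forward(m$params, f1$state, f1$y, cfg, TRUE)$y
  xp <- x[, , perm, , drop = FALSE]
  f2 <- tspnet:::.stem_forward(m$params, m$state, xp, cfg, TRUE)
  t2 <- tspnet:::.tdfe_forward(m$params, f2$state, f2$y, cfg, TRUE)$y
  expect_equal(t2, t1[, , perm, , drop = FALSE], tolerance = 1e-8)
})

test_that("spatial stage (pre-pooling sum) is equivariant to temporal permutations", {
  set.seed(44)
  x <- array(rnorm(4 * 6 * 4 * 2), c(4L, 6L, 4L, 2L))
  wts <- random_block_weights(4L, 4L, c(1L, 3L, 5L), seed = 45)
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  y1 <- residual_parallel_block(x, wts, axis = "spatial")
  y2 <- residual_parallel_block(x[, perm, , , drop = FALSE], wts, axis = "spatial")
  expect_equal(y2, y1[, perm, , , drop = FALSE], tolerance = 1e-8)
})

test_that("spatial reduction halves the electrode axis in both pooling modes", {
  for (mode in c("maxpool", "stride2")) {
    cfg <- tiny_model_config(sdfe_pooling_mode = mode)
    m <- tspnet_init(cfg)
    set.seed(46)
    x <- array(rnorm(4 * 12 * 4 * 2), c(4L, 12L, 4L, 2L))
    y <- sdfe_forward(x, m, train = TRUE)
    expect_equal(dim(y), c(5L, 12L, 2L, 2L))
  }
})

test_that("temporal decimation uses the smallest stride reaching the cap", {
  # reference geometry: 1500 samples decimated under a 64-column cap
  x <- array(rnorm(2 * 1500 * 1 * 1), c(2L, 1500L, 1L, 1L))
  y <- temporal_decimate(x, 64L)
  expect_equal(dim(y)[2L], 62L)  # stride 24: floor(1500 / 24)
  expect_equal(tspnet:::decimation_stride(1500L, 64L), 24L)
  # identity when already within the cap
  x2 <- array(rnorm(2 * 64), c(2L, 64L, 1L, 1L))
  expect_identical(temporal_decimate(x2, 64L), x2)
  # mean preservation on constant input
  xc <- array(3, c(1L, 12L, 1L, 1L))
  expect_true(all(temporal_decimate(xc, 4L) == 3))
})

test_that("disabling stages passes activations through unchanged", {
  cfg <- tiny_model_config(use_tdfe = FALSE)
  m <- tspnet_init(cfg)
  set.seed(47)
  x <- array(rnorm(2 * 12 * 4 * 2), c(2L, 12L, 4L, 2L))
  expect_identical(tdfe_forward(x, m), x)
  cfg2 <- tiny_model_config(use_sdfe = FALSE)
  m2 <- tspnet_init(cfg2)
  x2 <- array(rnorm(4 * 12 * 4 * 2), c(4L, 12L, 4L, 2L))
  expect_identical(sdfe_forward(x2, m2), x2)
})
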