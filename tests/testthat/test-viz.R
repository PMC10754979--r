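test_that("band-pass filtering passes its band and rejects DC and stop bands", {
  fs <- 128
  t0 <- (0:511) / fs
  mk <- function(f) {
    arr <- array(0, c(1L, 1L, 512L))
    arr[1, 1, ] <- sin(2 * pi * f * t0)
    epoch_set(arr, 0L, fs, "C3")
  }
  alpha <- band_definition("alpha", 7, 13)
  # 10 Hz tone through the alpha band survives
  out <- bandpass_filter_epochs(mk(10), alpha)
  expect_gte(max(abs(out$data[1, 1, 100:400])), 0.9)
  # 10 Hz tone through delta is crushed
  delta <- band_definition("delta", 0.5, 3)
  out2 <- bandpass_filter_epochs(mk(10), delta)
  expect_lte(max(abs(out2$data[1, 1, 100:400])), 0.1)
  # constant input is rejected by any band-pass (away from the forward and
  # backward filter transients at the epoch edges)
  arr <- array(1, c(1L, 1L, 2048L))
  dc <- epoch_set(arr, 0L, fs, "C3")
  out3 <- bandpass_filter_epochs(dc, alpha)
  expect_lt(max(abs(out3$data[1, 1, 600:1448])), 1e-3)
  expect_equal(out$labels, 0L)
})

test_that("the beta band clips at 0.45 fs with a warning and degenerate bands error", {
  es <- tiny_epochs(n_per_class = 1L)  # fs = 32
  expect_warning(bandpass_filter_epochs(es, "beta"), "clipped")
  low_fs <- es
  low_fs$fs <- 20
  expect_warning(expect_error(
    bandpass_filter_epochs(low_fs, band_definition("x", 9.5, 100)),
    "degenerate"), "clipped")
  expect_error(band_definition("bad", 5, 3), "low < high")
})

test_that("band-filtered broadband noise concentrates its energy in band", {
  set.seed(70)
  fs <- 128
  arr <- array(rnorm(2 * 1024), c(1L, 2L, 1024L))
  es <- epoch_set(arr, 0L, fs, c("C3", "C4"))
  bands <- default_bands()
  for (bi in seq_len(nrow(bands))) {
    out <- suppressWarnings(bandpass_filter_epochs(es, bands[bi, ]))
    v <- out$data[1, 1, ]
    p <- abs(fft(v))^2
    f <- (0:1023) * fs / 1024
    half <- f <= fs / 2
    lo <- bands$low[bi]
    hi <- min(bands$high[bi], 0.45 * fs)
    inband <- half & f >= lo * 0.8 & f <= hi * 1.25  # transition-band margin
    frac <- sum(p[inband]) / sum(p[half])
    expect_gt(frac, 0.99)
  }
})

test_that("correct-trial selection yields a subset with perfect accuracy", {
  cfg <- tiny_model_config()
  m <- tspnet_init(cfg)
  es <- tiny_epochs(n_per_class = 4L)
  tc <- predict_and_select_correct(m, es)
  if (n_trials(tc) > 0L) {
    expect_equal(evaluate_model(m, tc), 1.0)
  }
  # a constant-class predictor keeps exactly the trials of that class
  m0 <- m
  m0$params[["head.W"]][] <- 0
  m0$params[["head.b"]] <- c(1, rep(0, 5))
  tc0 <- predict_and_select_correct(m0, es)
  expect_equal(n_trials(tc0), n_trials(es) / 6L)
  expect_true(all(tc0$labels == 0L))
  # order is preserved
  expect_equal(tc0$labels, es$labels[es$labels == 0L])
})

test_that("class averaging handles symmetry and absent classes explicitly", {
  maps <- array(0, c(2L, 3L, 2L, 4L))
  maps[, , , 1L] <- 1
  maps[, , , 2L] <- 1
  maps[, , , 3L] <- 5
  maps[, , , 4L] <- -5
  labels <- c(0L, 0L, 2L, 2L)
  avg <- average_feature_maps_by_class(maps, labels)
  expect_equal(avg$class_0, array(1, c(2L, 3L, 2L)))
  expect_equal(avg$class_2, array(0, c(2L, 3L, 2L)))
  expect_null(avg$class_1)
  expect_null(avg$class_5)
})

test_that("electrode importance maps pooled positions back to electrode pairs", {
  m16 <- default_montage("dataset_I_16ch")
  cm <- array(abs(rnorm(4 * 5 * 8)), c(4L, 5L, 8L))
  sc <- electrode_importance(cm, m16)
  expect_length(sc, 16L)
  expect_named(sc, m16$channel_names)
  # paired electrodes share their pooled unit's score
  expect_equal(unname(sc[seq(1, 15, 2)]), unname(sc[seq(2, 16, 2)]))
  # a constant map scores all electrodes equally
  cmc <- array(1, c(4L, 5L, 8L))
  expect_equal(unname(electrode_importance(cmc, m16)), rep(1, 16))
  # full-resolution maps pass through unchanged in length
  cm16 <- array(abs(rnorm(4 * 5 * 16)), c(4L, 5L, 16L))
  expect_length(electrode_importance(cm16, m16), 16L)
  expect_error(electrode_importance(array(1, c(2L, 2L, 5L)), m16), "map onto")
})

test_that("feature extraction taps return the documented shapes", {
  cfg <- tiny_model_config()
  m <- tspnet_init(cfg)
  es <- tiny_epochs(n_per_class = 2L)
  sh <- tspnet_shapes(cfg)
  f_tspfe <- extract_features(m, es, tap = "tspfe")
  expect_equal(dim(f_tspfe), c(sh$tspfe, n_trials(es)))
  f_pre <- extract_features(m, es, tap = "pre_tspfe")
  expect_equal(dim(f_pre), c(sh$decimate, n_trials(es)))
  expect_equal(dim(f_tspfe)[1L], 2L * dim(f_pre)[1L])
  # identical trials give identical maps (evaluation determinism)
  es2 <- es
  es2$data[2L, , ] <- es2$data[1L, , ]
  f2 <- extract_features(m, es2, tap = "tspfe")
  expect_equal(f2[, , , 1L], f2[, , , 2L])
})

test_that("topography rendering writes a file and returns the scores", {
  m16 <- default_montage("dataset_I_16ch")
  sc <- setNames(runif(16), m16$channel_names)
  f <- tempfile(fileext = ".png")
  out <- plot_topomap(sc, m16, file = f)
  expect_true(file.exists(f))
  expect_gt(file.info(f)$size, 0)
  expect_equal(out, sc)
})

test_that("the class-band table covers detected classes for every band", {
  cfg <- tiny_model_config(n_input_channels = 16L)
  m <- tspnet_init(cfg)
  es <- tiny_epochs(n_per_class = 3L, n_channels = 16L, fs = 128)
  es$channel_names <- default_montage("dataset_I_16ch")$channel_names
  tab <- suppressWarnings(
    class_band_map(m, es, default_montage("dataset_I_16ch")))
  expect_true(all(c("class", "band", "electrode", "score") %in% names(tab)))
  expect_true(all(tab$band %in% default_bands()$name))
  expect_equal(length(unique(tab$electrode)), 16L)
  expect_true(all(is.finite(tab$score)))
})
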