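# Synthetic motor-imagery EEG: class-specific band-limited power modulation
# over motor-cortex electrodes riding on a 1/f background.

#' Synthetic generator configuration
#'
#' Describes one simulated recording campaign: montage profile, cohort and
#' trial counts, sampling, the amplitude of the class-specific band-limited
#' modulation relative to the background standard deviation (`effect_size`),
#' the 1/f background slope, optional 50 Hz line contamination, and the seed
#' that fully determines the output.
#'
#' @param profile `"dataset_I_16ch"` or `"dataset_II_61ch"`.
#' @param n_subjects Number of simulated subjects.
#' @param trials_per_class Trials per class per subject.
#' @param fs Sampling rate in Hz.
#' @param n_samples Samples per epoch (`round(duration * fs)`).
#' @param effect_size Non-negative amplitude of the class signal in units of
#'   background SD. `0` produces label-free noise.
#' @param noise_exponent Background spectral slope: PSD falls as
#'   `1/f^noise_exponent`.
#' @param line_noise_amplitude Amplitude of an additive 50 Hz component
#'   (0 disables it; recordings the generator emulates are notch-filtered at
#'   acquisition, so the default is off).
#' @param pure_tone If `TRUE`, class signals are fixed-frequency sinusoids at
#'   the centre of the class band (random phase per trial) instead of
#'   band-limited noise; used for visualization sanity checks.
#' @param seed Integer seed; identical configs give bit-identical epoch sets.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(profile = "dataset_I_16ch",
                         n_subjects = 1L,
                         trials_per_class = 60L,
                         fs = 500,
                         n_samples = 1500L,
                         effect_size = 1,
                         noise_exponent = 1,
                         line_noise_amplitude = 0,
                         pure_tone = FALSE,
                         seed = 1L) {
  stopifnot(effect_size >= 0, fs > 0, n_samples >= 8L,
            n_subjects >= 1L, trials_per_class >= 1L)
  m <- default_montage(profile)  # errors on unknown profile
  structure(list(
    profile = profile, n_subjects = as.integer(n_subjects),
    trials_per_class = as.integer(trials_per_class),
    fs = fs, n_samples = as.integer(n_samples),
    effect_size = effect_size, noise_exponent = noise_exponent,
    line_noise_amplitude = line_noise_amplitude,
    pure_tone = isTRUE(pure_tone),
    seed = as.integer(seed),
    montage = m
  ), class = "synth_config")
}

#' Full-scale generator configurations for the two dataset profiles
#'
#' Returns the configuration matching each recording campaign's stated
#' dimensions: profile I is 16 channels at 500 Hz, 1500 samples per epoch,
#' 300 trials per class for each of 10 subjects (18,000 epochs); profile II
#' is 61 channels, 60 trials per class for each of 15 subjects (5,400
#' epochs).
#'
#' @param profile `"dataset_I_16ch"` or `"dataset_II_61ch"`.
#' @param ... Overrides passed to [synth_config()] (e.g. a reduced
#'   `n_samples` when only epoch counts matter).
#' @return A `synth_config`.
#' @export
dataset_profile <- function(profile, ...) {
  base <- switch(profile,
    dataset_I_16ch = list(profile = profile, n_subjects = 10L,
                          trials_per_class = 300L, fs = 500, n_samples = 1500L),
    dataset_II_61ch = list(profile = profile, n_subjects = 15L,
                           trials_per_class = 60L, fs = 500, n_samples = 1500L),
    stop(sprintf("unknown dataset profile '%s'", profile))
  )
  do.call(synth_config, utils::modifyList(base, list(...)))
}

#' Desk-scale generator configuration
#'
#' A single-subject, 60-trials-per-class variant of profile I sampled at
#' 32 Hz over a 1.5 s epoch (48 samples), which resolves the theta, alpha
#' and (truncated) beta signature bands. This is the configuration the
#' package's own test protocol trains on; see the methods vignette for the
#' rationale behind the problem size.
#'
#' @param effect_size Class-signal amplitude in background-SD units
#'   (default 3, a strongly discriminable regime).
#' @param trials_per_class,n_samples,seed,pure_tone As in [synth_config()].
#' @param ... Further overrides passed to [synth_config()].
#' @return A `synth_config`.
#' @export
desk_synth_config <- function(effect_size = 3, trials_per_class = 60L,
                              n_samples = 48L, seed = 1L,
                              pure_tone = FALSE, ...) {
  synth_config(profile = "dataset_I_16ch", n_subjects = 1L,
               trials_per_class = trials_per_class, fs = 32,
               n_samples = n_samples, effect_size = effect_size,
               seed = seed, pure_tone = pure_tone, ...)
}

#' Class signature tables
#'
#' A signature table assigns each class a target electrode set, a frequency
#' band, and a modulation sign; the generator adds a band-limited process on
#' the target electrodes only. The default table mimics event-related
#' band-power modulation over the sensorimotor strip: the CytonDaisy montage
#' carries C3 and C4 over motor cortex, and the six classes are the six
#' distinct (electrode, band) pairs from \{C3, C4\} x \{delta 1-3 Hz,
#' theta 3-7 Hz, alpha 7-13 Hz\}.
#'
#' @param montage A [montage()]; signature electrodes must be present in it.
#' @return A data.frame with one row per class: `class`, `electrodes`
#'   (comma-separated), `band`, `low`, `high`, `sign`.
#' @details The six classes are the six distinct (electrode, band) pairs
#'   from \{C3, C4\} x \{theta 3-7 Hz, alpha 7-13 Hz, beta 13-30 Hz\} —
#'   alpha (mu) and beta are the classic sensorimotor ERD/ERS bands, theta
#'   adds a third separable rhythm. Bands are truncated at the Nyquist
#'   frequency automatically when a configuration samples below 60 Hz.
#' @export
default_signatures <- function(montage = default_montage("dataset_I_16ch")) {
  sig <- data.frame(
    class = 0:5,
    electrodes = c("C3", "C4", "C3", "C4", "C3", "C4"),
    band = c("alpha", "alpha", "theta", "theta", "beta", "beta"),
    low  = c(7, 7, 3, 3, 13, 13),
    high = c(13, 13, 7, 7, 30, 30),
    sign = rep(1, 6),
    stringsAsFactors = FALSE
  )
  .check_signatures(sig, montage)
}

#' @rdname default_signatures
#' @details `viz_signatures()` is a variant used by the visualization sanity
#'   protocol: six distinct single electrodes chosen so that no two classes
#'   share a spatial max-pool pair of the 16-channel layout (the topographic
#'   read-out cannot separate electrodes that were pooled together; see the
#'   methods vignette).
#' @export
viz_signatures <- function(montage = default_montage("dataset_I_16ch")) {
  sig <- data.frame(
    class = 0:5,
    electrodes = c("C3", "P7", "O1", "F3", "T7", "P3"),
    band = c("alpha", "theta", "alpha", "theta", "alpha", "theta"),
    low  = c(7, 3, 7, 3, 7, 3),
    high = c(13, 7, 13, 7, 13, 7),
    sign = rep(1, 6),
    stringsAsFactors = FALSE
  )
  .check_signatures(sig, montage)
}

.check_signatures <- function(sig, montage) {
  stopifnot(is.data.frame(sig),
            all(c("class", "electrodes", "band", "low", "high", "sign") %in% names(sig)))
  key <- paste(sig$electrodes, sig$band)
  if (anyDuplicated(key)) stop("class signatures must be pairwise distinct")
  els <- unique(unlist(strsplit(sig$electrodes, ",", fixed = TRUE)))
  missing <- setdiff(trimws(els), montage$channel_names)
  if (length(missing)) {
    stop(sprintf("signature electrode(s) not in montage: %s",
                 paste(missing, collapse = ", ")))
  }
  attr(sig, "montage") <- montage
  sig
}

# Frequency-domain synthesis of n_series independent series with amplitude
# profile g(f) (length n one-sided gains applied symmetrically). Returns
# [n_samples x n_series].
.spectral_noise <- function(n_samples, n_series, gain) {
  w <- matrix(stats::rnorm(n_samples * n_series), n_samples, n_series)
  wf <- stats::mvfft(w)
  y <- Re(stats::mvfft(wf * gain, inverse = TRUE)) / n_samples
  y
}

# Two-sided gain vector for FFT bins of length n at rate fs.
.fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  f <- k * fs / n
  pmin(f, fs - f)  # fold negative frequencies
}

#' Generate 1/f background noise
#'
#' Zero-mean noise whose power spectral density falls as
#' `1/f^noise_exponent`, synthesized by spectrally shaping white Gaussian
#' noise (zero-phase). Each channel is standardized to unit SD so that
#' `effect_size` elsewhere is expressed in background-SD units.
#'
#' @param n_channels,n_samples Array dimensions.
#' @param fs Sampling rate in Hz.
#' @param noise_exponent Spectral slope (0 = white).
#' @param seed Integer seed (deterministic output).
#' @return Numeric matrix `[n_channels, n_samples]`.
#' @export
generate_background <- function(n_channels, n_samples, fs, noise_exponent, seed) {
  stopifnot(n_channels >= 1, n_samples >= 8, fs > 0)
  with_seed(seed, {
    m <- .background_block(n_channels, n_samples, fs, noise_exponent)
    m
  })
}

# unseeded core so generate_epoch_set can draw many blocks from one stream
.background_block <- function(n_channels, n_samples, fs, noise_exponent) {
  f <- .fft_freqs(n_samples, fs)
  g <- rep(0, n_samples)
  nz <- f > 0
  g[nz] <- f[nz]^(-noise_exponent / 2)
  y <- .spectral_noise(n_samples, n_channels, g)
  y <- sweep(y, 2L, colMeans(y), "-")
  s <- sqrt(colSums(y^2) / (n_samples - 1L))
  s[s == 0] <- 1
  t(sweep(y, 2L, s, "/"))
}

# Band-limited unit-SD random-phase processes, [n_samples x n_series].
.narrowband_block <- function(n_samples, n_series, fs, low, high) {
  f <- .fft_freqs(n_samples, fs)
  g <- as.numeric(f >= low & f <= high)
  if (sum(g) == 0) {
    stop(sprintf("band [%g, %g] Hz contains no FFT bin at fs=%g, n=%d",
                 low, high, fs, n_samples))
  }
  y <- .spectral_noise(n_samples, n_series, g)
  s <- sqrt(colSums(sweep(y, 2L, colMeans(y), "-")^2) / (n_samples - 1L))
  s[s == 0] <- 1
  sweep(y, 2L, s, "/")
}

# Pure tones at band centre (kept below Nyquist), random phase per series,
# unit SD.
.tone_block <- function(n_samples, n_series, fs, low, high) {
  fc <- min((low + high) / 2, 0.45 * fs)
  t <- (0:(n_samples - 1)) / fs
  ph <- stats::runif(n_series, 0, 2 * pi)
  sapply(ph, function(p) sqrt(2) * sin(2 * pi * fc * t + p))
}

#' Generate the class-specific signal of one trial
#'
#' A band-limited random-phase oscillation inside the class's frequency band,
#' present only on the class's target electrodes and scaled by `effect_size`
#' (in background-SD units). All-zero when `effect_size = 0`.
#'
#' @param class_index Class index 0-5, must appear in `signatures`.
#' @param signatures A signature table from [default_signatures()] (or
#'   compatible).
#' @param n_samples,fs Epoch length and sampling rate.
#' @param effect_size Amplitude scale.
#' @param seed Integer seed.
#' @param pure_tone Use a fixed-frequency sinusoid at the band centre instead
#'   of band-limited noise.
#' @return Numeric matrix `[n_channels, n_samples]` over the signature
#'   table's montage.
#' @export
generate_class_signal <- function(class_index, signatures, n_samples, fs,
                                  effect_size, seed, pure_tone = FALSE) {
  m <- attr(signatures, "montage")
  row <- signatures[signatures$class == class_index, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("class %s missing from signature table", class_index))
  }
  n_channels <- length(m$channel_names)
  out <- matrix(0, n_channels, n_samples)
  if (effect_size == 0) return(out)
  els <- trimws(strsplit(row$electrodes, ",", fixed = TRUE)[[1L]])
  idx <- match(els, m$channel_names)
  with_seed(seed, {
    blk <- if (pure_tone) {
      .tone_block(n_samples, length(idx), fs, row$low, row$high)
    } else {
      .narrowband_block(n_samples, length(idx), fs, row$low, row$high)
    }
    out[idx, ] <- t(blk) * effect_size * row$sign
  })
  out
}

#' Generate a labeled synthetic epoch set
#'
#' Produces `n_subjects * 6 * trials_per_class` epochs with exactly balanced
#' labels: each trial is 1/f background noise on every channel plus the
#' class's band-limited signal on its target electrodes (plus an optional
#' 50 Hz line component). Identical configurations give bit-identical
#' output.
#'
#' @param config A [synth_config()].
#' @param signatures A signature table; defaults to
#'   [default_signatures()] on the config's montage.
#' @return An [epoch_set()] with per-trial `subject_id`.
#' @export
generate_epoch_set <- function(config, signatures = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(signatures)) signatures <- default_signatures(config$montage)
  m <- attr(signatures, "montage")
  nch <- length(m$channel_names)
  ns <- config$n_samples
  tpc <- config$trials_per_class
  n_classes <- nrow(signatures)
  total <- config$n_subjects * n_classes * tpc

  data <- array(0, c(total, nch, ns))
  labels <- integer(total)
  subjects <- integer(total)

  with_seed(config$seed, {
    i <- 0L
    for (s in seq_len(config$n_subjects)) {
      for (ci in seq_len(n_classes)) {
        row <- signatures[ci, ]
        els <- trimws(strsplit(row$electrodes, ",", fixed = TRUE)[[1L]])
        tgt <- match(els, m$channel_names)
        # background for all trials of this (subject, class) at once
        bg <- .background_block(nch * tpc, ns, config$fs, config$noise_exponent)
        dim(bg) <- c(nch, tpc, ns)
        if (config$effect_size > 0) {
          blk <- if (config$pure_tone) {
            .tone_block(ns, length(tgt) * tpc, config$fs, row$low, row$high)
          } else {
            .narrowband_block(ns, length(tgt) * tpc, config$fs, row$low, row$high)
          }
          blk <- array(blk, c(ns, length(tgt), tpc)) * config$effect_size * row$sign
          for (e in seq_along(tgt)) {
            bg[tgt[e], , ] <- bg[tgt[e], , ] + t(blk[, e, ])
          }
        }
        if (config$line_noise_amplitude > 0 && 50 < config$fs / 2) {
          t0 <- (0:(ns - 1)) / config$fs
          ph <- stats::runif(tpc, 0, 2 * pi)
          for (tr in seq_len(tpc)) {
            line <- config$line_noise_amplitude * sin(2 * pi * 50 * t0 + ph[tr])
            bg[, tr, ] <- sweep(bg[, tr, , drop = FALSE][, 1L, ], 2L, -line, "+")
          }
        }
        rng <- i + seq_len(tpc)
        data[rng, , ] <- aperm(bg, c(2L, 1L, 3L))
        labels[rng] <- row$class
        subjects[rng] <- s
        i <- i + tpc
      }
    }
  })
  epoch_set(data, labels, config$fs, m$channel_names, subject_id = subjects)
}
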