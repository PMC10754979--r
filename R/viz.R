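# Feature visualization by signal band occlusion: keep one canonical
# frequency band of the correctly-classified test trials at a time, re-run
# the feature extractor, average per class, and map the activation back to
# electrodes as a scalp topography.

#' Canonical frequency bands
#'
#' The four bands of the visualization algorithm: delta 0.5-3 Hz, theta
#' 3-7 Hz, alpha 7-13 Hz, beta 13-200 Hz. Beta's high edge is kept verbatim
#' where the sampling rate allows it and clipped to `0.45 * fs` otherwise
#' (see [bandpass_filter_epochs()]).
#'
#' @return data.frame with columns `name`, `low`, `high`.
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             low = c(0.5, 3, 7, 13),
             high = c(3, 7, 13, 200),
             stringsAsFactors = FALSE)
}

#' Band definition
#'
#' @param name Band name.
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @return One-row data.frame compatible with [default_bands()].
#' @export
band_definition <- function(name, low, high) {
  if (!(low > 0 && high > low)) stop("band edges must satisfy 0 < low < high")
  data.frame(name = name, low = low, high = high, stringsAsFactors = FALSE)
}

#' Keep correctly classified trials
#'
#' Runs the classifier on a labeled test set and returns the subset whose
#' predicted class equals the label, order preserved. Accuracy on the
#' returned subset is exactly 1 by construction.
#'
#' @param model A trained `tspnet_model`.
#' @param test A labeled [epoch_set()].
#' @return An [epoch_set()] of the correctly recognized trials (possibly
#'   empty, with a warning).
#' @export
predict_and_select_correct <- function(model, test) {
  pred <- predict_classes(model, test)
  keep <- which(pred == test$labels)
  if (length(keep) == 0L) {
    warning("no correctly classified trials; downstream maps will be empty")
  }
  subset_epochs(test, keep)
}

#' Zero-phase band-pass filtering of epochs
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero-phase) to every channel of every trial. A band edge at or above
#' 0.45 of the sampling rate is clipped there with a warning; a band left
#' degenerate by clipping is an error.
#'
#' @param epochs An [epoch_set()].
#' @param band One-row band data.frame ([band_definition()]) or a band name
#'   from [default_bands()].
#' @param order Butterworth order (default 4).
#' @return The filtered [epoch_set()] (labels unchanged).
#' @export
bandpass_filter_epochs <- function(epochs, band, order = 4L) {
  validate_epoch_set(epochs)
  if (is.character(band)) {
    bands <- default_bands()
    band <- bands[bands$name == band, , drop = FALSE]
    if (nrow(band) != 1L) stop("unknown band name")
  }
  low <- band$low
  high <- band$high
  lim <- 0.45 * epochs$fs
  if (high > lim) {
    warning(sprintf("band high edge %g Hz clipped to %g Hz (0.45 * fs)",
                    high, lim))
    high <- lim
  }
  if (low >= high) {
    stop(sprintf("band [%g, %g] Hz degenerate after Nyquist clipping", low, high))
  }
  bf <- signal::butter(order, c(low, high) / (epochs$fs / 2), type = "pass")
  d <- dim(epochs$data)
  m <- matrix(aperm(epochs$data, c(3L, 1L, 2L)), nrow = d[3L])
  for (j in seq_len(ncol(m))) {
    m[, j] <- signal::filtfilt(bf, m[, j])
  }
  epochs$data <- aperm(array(m, c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L))
  epochs
}

#' Band-limited feature extraction
#'
#' Step 4 of the visualization algorithm: runs the trained network's
#' feature extractor on band-filtered trials up to a tap point
#' (`"tspfe"` by default; `"pre_tspfe"` supports the before/after-head
#' comparison).
#'
#' @param model A trained `tspnet_model`.
#' @param banded A band-filtered [epoch_set()] (see
#'   [bandpass_filter_epochs()]). Filter *normalized* trials: the
#'   band-filtered data enters the network as is, because its per-channel
#'   variance — the fraction of each electrode's energy inside the band —
#'   is exactly the quantity the occlusion read-out localizes (re-scoring
#'   here would equalize the channels and erase it).
#' @param tap Tap point, as in [extract_features()].
#' @return List with `maps` (`[C, W, H, n]` activations) and `labels`.
#' @export
extract_band_features <- function(model, banded, tap = "tspfe") {
  if (n_trials(banded) == 0L) {
    return(list(maps = NULL, labels = integer(0)))
  }
  maps <- extract_features(model, banded, tap = tap)
  list(maps = maps, labels = banded$labels)
}

#' Average feature maps per class
#'
#' Arithmetic mean of the per-trial activation maps within each class.
#' Classes absent from the input yield an explicit `NULL` entry rather than
#' silent zeros.
#'
#' @param maps Activation array `[C, W, H, n]` (from
#'   [extract_band_features()]).
#' @param labels Class labels aligned with the trials.
#' @param n_classes Number of classes.
#' @return Named list `class_0` ... with mean `[C, W, H]` arrays or `NULL`.
#' @export
average_feature_maps_by_class <- function(maps, labels, n_classes = 6L) {
  out <- vector("list", n_classes)
  names(out) <- paste0("class_", seq_len(n_classes) - 1L)
  if (is.null(maps)) return(out)
  stopifnot(dim(maps)[4L] == length(labels))
  for (cl in seq_len(n_classes) - 1L) {
    idx <- which(labels == cl)
    if (length(idx) == 0L) next
    m <- maps[, , , idx, drop = FALSE]
    out[[cl + 1L]] <- array(rowMeans(matrix(m, ncol = length(idx))),
                            dim(maps)[1:3])
  }
  out
}

#' Electrode importance scores from a class-average map
#'
#' Collapses the feature-channel and temporal axes by mean absolute
#' activation, leaving one score per spatial position, then maps the
#' reduced spatial extent back to electrodes: after spatial pooling each
#' position represents a pair of adjacent electrodes, and its score is
#' assigned to both members (piecewise-constant upsampling — pooling
#' genuinely discards within-pair resolution, so no gradient is invented
#' inside a pair). An odd trailing electrode inherits the last position's
#' score.
#'
#' @param class_map Mean activation array `[C, W, H']`.
#' @param montage The recording [montage()] (original electrode count).
#' @return Named numeric vector of per-electrode scores.
#' @export
electrode_importance <- function(class_map, montage) {
  if (is.null(class_map)) stop("class map is empty (class absent)")
  d <- dim(class_map)
  n_el <- length(montage$channel_names)
  hp <- d[3L]
  if (!(hp == n_el || hp == n_el %/% 2L)) {
    stop(sprintf("spatial extent %d does not map onto %d electrodes", hp, n_el))
  }
  sc <- apply(abs(class_map), 3L, mean)
  scores <- if (hp == n_el) sc else {
    up <- rep(sc, each = 2L)
    if (n_el %% 2L == 1L) up <- c(up, sc[hp])
    up
  }
  names(scores) <- montage$channel_names
  scores
}

#' Scalp topography of electrode scores
#'
#' Renders an interpolated disc image (inverse-distance weighting on a
#' regular grid, masked to the unit disc) with electrode markers, and
#' returns the score vector invisibly. Optionally writes a PNG.
#'
#' @param scores Named per-electrode scores (see [electrode_importance()]).
#' @param montage The [montage()] the scores refer to.
#' @param file Optional PNG path; when `NULL`, draws on the current device.
#' @param main Plot title.
#' @param grid_n Interpolation grid resolution.
#' @return `scores`, invisibly.
#' @export
plot_topomap <- function(scores, montage, file = NULL, main = "", grid_n = 67L) {
  stopifnot(length(scores) == length(montage$channel_names))
  pos <- montage$positions
  gx <- seq(-1, 1, length.out = grid_n)
  gy <- seq(-1, 1, length.out = grid_n)
  img <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n)) {
    for (j in seq_len(grid_n)) {
      if (gx[i]^2 + gy[j]^2 > 1) next
      d2 <- (pos[, 1L] - gx[i])^2 + (pos[, 2L] - gy[j])^2
      if (any(d2 < 1e-12)) {
        img[i, j] <- scores[which.min(d2)]
      } else {
        w <- 1 / d2^1.5
        img[i, j] <- sum(w * scores) / sum(w)
      }
    }
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 480, height = 480)
    on.exit(grDevices::dev.off())
  }
  graphics::image(gx, gy, img, asp = 1, axes = FALSE, xlab = "", ylab = "",
                  main = main, col = grDevices::hcl.colors(64, "YlOrRd",
                                                           rev = TRUE))
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th))
  graphics::points(pos[, 1L], pos[, 2L], pch = 21, bg = "white", cex = 0.9)
  invisible(scores)
}

#' Class-by-band topography table
#'
#' The full visualization pipeline: select correctly classified trials,
#' band-pass each canonical band, extract features at the tap point,
#' average per class, and score electrodes. Returns tidy scores suitable
#' for CSV export and for [plot_topomap()].
#'
#' @param model A trained `tspnet_model`.
#' @param test A labeled [epoch_set()], normalized as at training time.
#' @param montage The recording [montage()].
#' @param bands Bands data.frame (default [default_bands()]).
#' @param tap Tap point (default `"tspfe"`).
#' @param contrast Score each class against the across-class mean map of
#'   the band (default): activation shared by every class — overall
#'   network energy allocation — cancels, leaving the class-distinctive
#'   pattern. `FALSE` scores the plain per-class average.
#' @return data.frame with columns `class`, `band`, `electrode`, `score`
#'   (classes with no correctly classified trial are absent).
#' @export
class_band_map <- function(model, test, montage, bands = default_bands(),
                           tap = "tspfe", contrast = TRUE) {
  tc <- predict_and_select_correct(model, test)
  out <- list()
  for (bi in seq_len(nrow(bands))) {
    banded <- suppressWarnings(bandpass_filter_epochs(tc, bands[bi, ]))
    feats <- extract_band_features(model, banded, tap = tap)
    avg <- average_feature_maps_by_class(feats$maps, feats$labels)
    present <- !vapply(avg, is.null, logical(1L))
    if (!any(present)) next
    grand <- Reduce(`+`, avg[present]) / sum(present)
    for (cl in seq_along(avg) - 1L) {
      cm <- avg[[cl + 1L]]
      if (is.null(cm)) next
      sc <- electrode_importance(if (contrast) cm - grand else cm, montage)
      out[[length(out) + 1L]] <- data.frame(
        class = cl, band = bands$name[bi],
        electrode = names(sc), score = unname(sc),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
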