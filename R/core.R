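#' @keywords internal
#' @useDynLib tspnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Class index <-> name mapping is fixed package-wide (0-based indices, as
# stored in epoch containers and labels).
.CLASS_NAMES <- c(
  "hand open", "hand close",
  "forearm supination", "forearm pronation",
  "elbow flexion", "elbow extension"
)

#' Motor-imagery class label table
#'
#' The six upper-limb motor-imagery categories decoded by the network, with
#' their fixed integer indices. Labels in an [epoch_set()] are these indices.
#'
#' @return A data.frame with columns `index` (0-5) and `name`.
#' @export
#' @examples
#' class_labels()
class_labels <- function() {
  data.frame(index = 0:5, name = .CLASS_NAMES, stringsAsFactors = FALSE)
}

#' Construct a labeled epoch set
#'
#' The canonical in-memory container for epoched multichannel EEG: a numeric
#' array of `n_trials x n_channels x n_samples`, one integer class label in
#' `0..5` per trial, the sampling rate, and electrode names.
#'
#' @param data Numeric array `[n_trials, n_channels, n_samples]`.
#' @param labels Integer vector of class indices in `0..5`, length `n_trials`.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_names Character vector of electrode labels, length
#'   `n_channels`.
#' @param subject_id Optional per-trial subject identifier (scalar or length
#'   `n_trials`).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, fs, channel_names, subject_id = NULL) {
  x <- structure(
    list(
      data = data, labels = as.integer(labels), fs = fs,
      channel_names = as.character(channel_names),
      subject_id = subject_id
    ),
    class = "epoch_set"
  )
  validate_epoch_set(x)
}

#' Validate an epoch set
#'
#' Checks shape coherence, label range, sampling rate and finiteness. Called
#' by every constructor and by the container reader; errors name the first
#' offending trial/channel.
#'
#' @param x An `epoch_set`.
#' @return `x`, invisibly validated (returned unchanged).
#' @export
validate_epoch_set <- function(x) {
  if (!inherits(x, "epoch_set")) stop("not an epoch_set")
  d <- dim(x$data)
  if (length(d) != 3L) stop("epoch data must be a 3-d array [trials, channels, samples]")
  if (length(x$labels) != d[1L]) {
    stop(sprintf("label length %d does not match %d trials", length(x$labels), d[1L]))
  }
  bad <- which(x$labels < 0L | x$labels > 5L)
  if (length(bad) > 0L) {
    stop(sprintf("invalid class label %d at trial %d (must be 0..5)",
                 x$labels[bad[1L]], bad[1L]))
  }
  if (!is.numeric(x$fs) || length(x$fs) != 1L || !is.finite(x$fs) || x$fs <= 0) {
    stop("fs must be a positive finite scalar")
  }
  if (length(x$channel_names) != d[2L]) {
    stop(sprintf("%d channel names for %d channels", length(x$channel_names), d[2L]))
  }
  if (anyNA(x$data) || !all(is.finite(x$data))) {
    idx <- which(!is.finite(x$data))[1L]
    ai <- arrayInd(idx, d)
    stop(sprintf("non-finite value at trial %d, channel %d, sample %d",
                 ai[1L], ai[2L], ai[3L]))
  }
  x
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat("  classes:", paste(sprintf("%d:%d", 0:5, tabulate(x$labels + 1L, 6L)),
                          collapse = " "), "\n")
  invisible(x)
}

#' Number of trials in an epoch set
#' @param x An `epoch_set`.
#' @return Integer trial count.
#' @export
n_trials <- function(x) dim(x$data)[1L]

#' Subset an epoch set by trial index
#' @param x An `epoch_set`.
#' @param i Integer trial indices to keep.
#' @return An `epoch_set` with the selected trials, order preserved.
#' @export
subset_epochs <- function(x, i) {
  epoch_set(
    data = x$data[i, , , drop = FALSE],
    labels = x$labels[i],
    fs = x$fs,
    channel_names = x$channel_names,
    subject_id = if (length(x$subject_id) == n_trials(x)) x$subject_id[i] else x$subject_id
  )
}

#' Per-trial, per-channel z-scoring of epochs
#'
#' Standardizes every channel of every trial to zero mean and unit standard
#' deviation along time (the package's input normalization for training;
#' standard practice for EEG convolutional networks). Channels with zero
#' variance map to all-zeros. Idempotent within numerical tolerance.
#'
#' @param epochs An `epoch_set`.
#' @return The normalized `epoch_set` (labels unchanged).
#' @export
normalize_epochs <- function(epochs) {
  validate_epoch_set(epochs)
  d <- dim(epochs$data)
  m <- matrix(aperm(epochs$data, c(3L, 1L, 2L)), nrow = d[3L])  # samples x (trial*channel)
  mu <- colMeans(m)
  m <- sweep(m, 2L, mu, "-")
  sd1 <- sqrt(colSums(m^2) / (d[3L] - 1L))
  sd1[sd1 == 0] <- Inf  # zero-variance channel -> all zeros
  m <- sweep(m, 2L, sd1, "/")
  epochs$data <- aperm(array(m, c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L))
  epochs
}

# ---------------------------------------------------------------------------
# Montages

# Row-wise 10-20 scalp layout: each row has a front-back coordinate y and a
# half-width w; electrodes are spread evenly across [-w, w]. All positions lie
# inside the unit disc (2-D projection used for topographic maps).
.MONTAGE_ROWS <- list(
  list(y =  0.82, w = 0.26, names = c("Fp1", "Fpz", "Fp2")),
  list(y =  0.68, w = 0.50, names = c("AF7", "AF3", "AFz", "AF4", "AF8")),
  list(y =  0.45, w = 0.72, names = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")),
  list(y =  0.22, w = 0.85, names = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8")),
  list(y =  0.00, w = 0.90, names = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8")),
  list(y = -0.22, w = 0.85, names = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8")),
  list(y = -0.45, w = 0.72, names = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8")),
  list(y = -0.68, w = 0.50, names = c("PO7", "PO3", "POz", "PO4", "PO8")),
  list(y = -0.82, w = 0.26, names = c("O1", "Oz", "O2"))
)

.montage_master <- function() {
  out <- do.call(rbind, lapply(.MONTAGE_ROWS, function(r) {
    n <- length(r$names)
    x <- if (n == 1L) 0 else seq(-r$w, r$w, length.out = n)
    data.frame(name = r$names, x = x, y = r$y, stringsAsFactors = FALSE)
  }))
  rownames(out) <- out$name
  out
}

# OpenBCI CytonDaisy default 16-site 10-20 assignment, in board channel order.
.CYTON_DAISY_16 <- c(
  "Fp1", "Fp2", "C3", "C4", "P7", "P8", "O1", "O2",
  "F7", "F8", "F3", "F4", "T7", "T8", "P3", "P4"
)

#' Construct a montage
#'
#' An ordered set of electrode names with 2-D scalp coordinates (unit-disc
#' projection of 10-20 positions).
#'
#' @param channel_names Character vector of unique electrode labels.
#' @param positions Numeric matrix `[n, 2]` of (x, y) positions in the unit
#'   disc, rows aligned with `channel_names`.
#' @return An object of class `montage`.
#' @export
montage <- function(channel_names, positions) {
  channel_names <- as.character(channel_names)
  positions <- as.matrix(positions)
  if (anyDuplicated(channel_names)) stop("duplicate electrode names in montage")
  if (nrow(positions) != length(channel_names) || ncol(positions) != 2L) {
    stop("positions must be an [n x 2] matrix aligned with channel_names")
  }
  r <- sqrt(rowSums(positions^2))
  if (any(r > 1 + 1e-9)) {
    stop(sprintf("electrode %s lies outside the unit disc",
                 channel_names[which.max(r)]))
  }
  dimnames(positions) <- list(channel_names, c("x", "y"))
  structure(list(channel_names = channel_names, positions = positions),
            class = "montage")
}

#' Built-in montages for the two dataset profiles
#'
#' `dataset_I_16ch` is the OpenBCI CytonDaisy default 16-site 10-20 layout in
#' board channel order (the amplifier used for the 16-channel recordings);
#' `dataset_II_61ch` is a 61-electrode extended 10-20 layout covering frontal,
#' central, parietal, temporal and occipital rows.
#'
#' @param profile One of `"dataset_I_16ch"`, `"dataset_II_61ch"`.
#' @return A [montage()].
#' @export
#' @examples
#' m <- default_montage("dataset_I_16ch")
#' m$channel_names
default_montage <- function(profile) {
  master <- .montage_master()
  names <- switch(profile,
    dataset_I_16ch = .CYTON_DAISY_16,
    dataset_II_61ch = master$name,
    stop(sprintf("unknown dataset profile '%s'", profile))
  )
  montage(names, as.matrix(master[names, c("x", "y")]))
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d electrodes: %s ...\n", length(x$channel_names),
              paste(utils::head(x$channel_names, 6L), collapse = " ")))
  invisible(x)
}

#' Export a montage as tab-separated text
#'
#' Writes one `name<TAB>x<TAB>y` line per electrode.
#'
#' @param m A [montage()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(m, path) {
  df <- data.frame(name = m$channel_names,
                   x = m$positions[, 1L], y = m$positions[, 2L])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Run a block with a deterministic, restored RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
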