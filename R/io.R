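# Epoch container (HDF5) and report export.

.CONTAINER_SCHEMA <- "tspnet-epochs-v1"

#' Write an epoch set to an HDF5 container
#'
#' Self-describing layout: `/data` (trials x channels x samples), `/labels`,
#' `/fs`, `/channel_names`, `/class_names`, `/subject_id` (when per-trial
#' identifiers exist), `/schema`, and a mandatory `/provenance` JSON block
#' (generator configuration or import source, package version, seed).
#'
#' @param epochs An [epoch_set()].
#' @param path Output file path (`.h5`).
#' @param provenance Named list describing where the data came from
#'   (mandatory; e.g. `list(generator = "...", seed = 1)`). The package
#'   version is added automatically.
#' @param overwrite Overwrite an existing file (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_epoch_container <- function(epochs, path, provenance,
                                  overwrite = FALSE) {
  validate_epoch_set(epochs)
  if (missing(provenance) || is.null(provenance) || !length(provenance)) {
    stop("provenance is mandatory: describe the generator config or source")
  }
  if (file.exists(path)) {
    if (!overwrite) stop(sprintf("'%s' exists; use overwrite = TRUE", path))
    unlink(path)
  }
  provenance$package_version <- as.character(utils::packageVersion("tspnet"))
  rhdf5::h5createFile(path)
  rhdf5::h5write(epochs$data, path, "data")
  rhdf5::h5write(epochs$labels, path, "labels")
  rhdf5::h5write(epochs$fs, path, "fs")
  rhdf5::h5write(epochs$channel_names, path, "channel_names")
  rhdf5::h5write(.CLASS_NAMES, path, "class_names")
  if (!is.null(epochs$subject_id)) {
    rhdf5::h5write(as.integer(epochs$subject_id), path, "subject_id")
  }
  rhdf5::h5write(.CONTAINER_SCHEMA, path, "schema")
  rhdf5::h5write(as.character(jsonlite::toJSON(provenance, auto_unbox = TRUE)),
                 path, "provenance")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read an epoch set from an HDF5 container
#'
#' Validates the schema tag and the reconstructed epoch set (shape
#' coherence, label range, finiteness); a violation produces a diagnostic
#' naming the first offending element.
#'
#' @param path Container path written by [write_epoch_container()].
#' @return An [epoch_set()] with a `provenance` attribute.
#' @export
read_epoch_container <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  on.exit(rhdf5::h5closeAll())
  contents <- rhdf5::h5ls(path)$name
  if (!("schema" %in% contents)) {
    stop("not an epoch container (missing schema tag)")
  }
  schema <- as.character(rhdf5::h5read(path, "schema"))
  if (schema != .CONTAINER_SCHEMA) {
    stop(sprintf("schema mismatch: found '%s', this reader handles '%s'",
                 schema, .CONTAINER_SCHEMA))
  }
  es <- epoch_set(
    data = rhdf5::h5read(path, "data"),
    labels = as.integer(rhdf5::h5read(path, "labels")),
    fs = as.numeric(rhdf5::h5read(path, "fs")),
    channel_names = as.character(rhdf5::h5read(path, "channel_names")),
    subject_id = if ("subject_id" %in% contents) {
      as.integer(rhdf5::h5read(path, "subject_id"))
    } else NULL
  )
  if ("provenance" %in% contents) {
    attr(es, "provenance") <-
      jsonlite::fromJSON(as.character(rhdf5::h5read(path, "provenance")))
  }
  es
}

#' Export an evaluation report or ablation table
#'
#' JSON carries full precision; CSV renders accuracies in percent with one
#' decimal (mean +/- SD layout of the reference tables). Field order is
#' deterministic.
#'
#' @param report An `eval_report`, an [ablation_matrix()] result, or a tidy
#'   scores data.frame from [class_band_map()].
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (inherits(report, "eval_report")) {
    payload <- list(
      accuracies = report$accuracies,
      accuracies_pct = 100 * report$accuracies,
      mean_pct = 100 * report$mean,
      sd_pct = 100 * ifelse(is.na(report$sd), 0, report$sd),
      seeds = report$seeds,
      config_fingerprint = report$config_fingerprint
    )
    if (format == "json") {
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    } else {
      df <- data.frame(
        partition = seq_along(report$accuracies),
        accuracy_pct = sprintf("%.1f", 100 * report$accuracies)
      )
      df <- rbind(df, data.frame(partition = "mean",
                                 accuracy_pct = sprintf("%.1f", payload$mean_pct)),
                  data.frame(partition = "sd",
                             accuracy_pct = sprintf("%.1f", payload$sd_pct)))
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    }
  } else if (is.list(report) && !is.null(report$table)) {
    if (format == "json") {
      jsonlite::write_json(report$table, path, auto_unbox = TRUE, digits = NA)
    } else {
      df <- report$table
      df$mean <- sprintf("%.1f", 100 * df$mean)
      df$sd <- sprintf("%.1f", 100 * df$sd)
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    }
  } else if (is.data.frame(report)) {
    if (format == "json") {
      jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
    } else {
      utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
    }
  } else {
    stop("unknown report type")
  }
  invisible(path)
}

#' Read an architecture configuration from JSON or YAML
#'
#' The file holds any subset of [tspnet_config()] arguments; unspecified
#' fields take their defaults.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A `tspnet_config`.
#' @export
read_model_config <- function(path) {
  fields <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configuration requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  do.call(tspnet_config, fields)
}

#' Save and load model checkpoints
#'
#' One file holds the weights, batch-norm state, configuration, optimizer
#' profile and loss history; loading restores a model whose predictions
#' are bit-identical to the saved one.
#'
#' @param model A `tspnet_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` invisibly for the writer; the restored `tspnet_model`
#'   for the reader.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "tspnet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "tspnet_model")) stop("not a model checkpoint")
  model
}
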