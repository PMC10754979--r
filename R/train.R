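# Training and evaluation protocol: stratified 70/30 splits repeated over
# shuffles, ADAM with gradient clipping and step-decay learning rate,
# accuracy statistics, pooled-variance t-tests, ablation matrix.

#' Optimizer profiles
#'
#' `"paper"` is the reference ADAM profile: initial learning rate 0.001,
#' gradient threshold 1, 1000 epochs maximum, mini-batch 64, learning rate
#' dropped by a factor of 0.1 every 500 epochs, squared-gradient decay 0.999
#' and gradient decay 0.9. `"desk"` keeps every ADAM constant but trains for
#' 30 epochs with mini-batch 32, the scale used by the package's own test
#' protocol (see the methods vignette).
#'
#' @param name `"paper"` or `"desk"`.
#' @param ... Field overrides (e.g. `max_epochs`).
#' @return An object of class `optimizer_profile`.
#' @export
optimizer_profile <- function(name = c("paper", "desk"), ...) {
  name <- match.arg(name)
  p <- list(
    initial_learn_rate = 0.001,
    gradient_threshold = 1,
    max_epochs = 1000L,
    mini_batch_size = 64L,
    learn_rate_drop_factor = 0.1,
    learn_rate_drop_period = 500L,
    squared_gradient_decay = 0.999,
    gradient_decay = 0.9
  )
  if (name == "desk") {
    p$max_epochs <- 30L
    p$mini_batch_size <- 32L
  }
  p <- utils::modifyList(p, list(...))
  stopifnot(p$initial_learn_rate > 0, p$gradient_threshold > 0,
            p$max_epochs >= 1, p$mini_batch_size >= 1,
            p$learn_rate_drop_factor > 0, p$learn_rate_drop_factor <= 1,
            p$learn_rate_drop_period >= 1,
            p$squared_gradient_decay > 0, p$squared_gradient_decay < 1,
            p$gradient_decay > 0, p$gradient_decay < 1)
  structure(c(p, list(name = name)), class = "optimizer_profile")
}

#' Learning rate at a given epoch
#'
#' Step decay: `initial * drop_factor^floor(epoch / drop_period)`, so the
#' first drop takes effect at `epoch = drop_period` (0.001 becomes 1e-4 at
#' epoch 500 under the reference profile).
#'
#' @param profile An [optimizer_profile()].
#' @param epoch Epoch number (1-based).
#' @return Learning rate.
#' @export
learn_rate_at <- function(profile, epoch) {
  profile$initial_learn_rate *
    profile$learn_rate_drop_factor^(epoch %/% profile$learn_rate_drop_period)
}

#' Stratified train/test split
#'
#' Splits a balanced epoch set per class: `floor(train_fraction * n_c)`
#' trials of every class go to the training partition, the rest to the test
#' partition. Both partitions stay balanced, are disjoint, and their union
#' is the input; the draw is deterministic given the seed.
#'
#' @param epochs A balanced [epoch_set()].
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.7).
#' @param seed Integer seed.
#' @return List with `train` and `test` epoch sets.
#' @export
stratified_split <- function(epochs, train_fraction = 0.7, seed = 1L) {
  validate_epoch_set(epochs)
  counts <- table(epochs$labels)
  if (any(counts < 2L)) {
    stop(sprintf("class %s has fewer than 2 trials", names(counts)[counts < 2L][1L]))
  }
  tr_idx <- integer(0)
  with_seed(seed, {
    for (cl in as.integer(names(counts))) {
      idx <- which(epochs$labels == cl)
      n_tr <- floor(train_fraction * length(idx))
      tr_idx <- c(tr_idx, sample(idx, n_tr))
    }
  })
  tr_idx <- sort(tr_idx)
  te_idx <- setdiff(seq_len(n_trials(epochs)), tr_idx)
  list(train = subset_epochs(epochs, tr_idx),
       test = subset_epochs(epochs, te_idx))
}

# Global L2-norm gradient clipping.
.clip_grads <- function(grads, threshold) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1L))))
  if (is.finite(total) && total > threshold) {
    sc <- threshold / total
    grads <- lapply(grads, function(g) g * sc)
  }
  grads
}

#' Train the network with ADAM
#'
#' Mini-batch ADAM with bias correction, global gradient-norm clipping at
#' the profile's threshold, and step-decay learning rate. Weight
#' initialization and shuffling are fully determined by `seed`. Aborts with
#' a diagnostic naming the offending epoch/batch if the loss turns
#' non-finite. The training data is expected to be class-balanced and
#' normalized (see [normalize_epochs()]).
#'
#' @param train A balanced, normalized [epoch_set()].
#' @param config A [tspnet_config()] matching the epoch geometry.
#' @param profile An [optimizer_profile()].
#' @param seed Integer seed (initialization + batch shuffling).
#' @param class_weights Optional positive per-class loss weights.
#' @param verbose Print per-epoch loss.
#' @return A `tspnet_model` with a `loss_history` element (mean batch loss
#'   per epoch) and the training seed.
#' @export
train_model <- function(train, config, profile = optimizer_profile("desk"),
                        seed = 1L, class_weights = NULL, verbose = FALSE) {
  validate_epoch_set(train)
  config$seed <- as.integer(seed)
  model <- tspnet_init(config)
  x_all <- epochs_to_input(train)
  labels <- train$labels
  n <- length(labels)
  mstate <- lapply(model$params, function(p) { p[] <- 0; p })
  vstate <- mstate
  t_step <- 0L
  loss_history <- numeric(profile$max_epochs)
  b1 <- profile$gradient_decay
  b2 <- profile$squared_gradient_decay
  with_seed(seed + 1L, {
    for (epoch in seq_len(profile$max_epochs)) {
      lr <- learn_rate_at(profile, epoch)
      ord <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1L, n, by = profile$mini_batch_size)) {
        idx <- ord[start:min(start + profile$mini_batch_size - 1L, n)]
        xb <- x_all[, , , idx, drop = FALSE]
        lg <- tspnet_loss_grad(model, xb, labels[idx], class_weights)
        if (!is.finite(lg$loss)) {
          stop(sprintf("non-finite loss at epoch %d, batch starting at trial %d",
                       epoch, start))
        }
        model$state <- lg$state
        grads <- .clip_grads(lg$grads, profile$gradient_threshold)
        t_step <- t_step + 1L
        bc1 <- 1 - b1^t_step
        bc2 <- 1 - b2^t_step
        for (nm in names(model$params)) {
          g <- grads[[nm]]
          mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
          vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g^2
          mhat <- mstate[[nm]] / bc1
          vhat <- vstate[[nm]] / bc2
          model$params[[nm]] <- model$params[[nm]] -
            lr * mhat / (sqrt(vhat) + 1e-8)
        }
        batch_losses <- c(batch_losses, lg$loss)
      }
      loss_history[epoch] <- mean(batch_losses)
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2e  loss %.4f", epoch, lr,
                        loss_history[epoch]))
      }
    }
  })
  model$loss_history <- loss_history
  model$seed <- as.integer(seed)
  model$profile <- profile
  model
}

#' Classification accuracy on a test set
#'
#' Fraction of trials whose argmax class equals the label (argmax ties break
#' toward the lowest class index).
#'
#' @param model A trained `tspnet_model`.
#' @param test A non-empty [epoch_set()].
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_model <- function(model, test) {
  if (n_trials(test) == 0L) stop("test set is empty")
  mean(predict_classes(model, test) == test$labels)
}

#' Repeated stratified holdout evaluation
#'
#' Runs split -> normalize -> train -> evaluate over `n_partitions` random
#' shuffles (fresh 70/30 draw each time, seeds `base_seed .. base_seed +
#' n_partitions - 1`) and reports the per-partition accuracies with their
#' mean and sample standard deviation.
#'
#' @param epochs A balanced [epoch_set()].
#' @param config A [tspnet_config()].
#' @param profile An [optimizer_profile()].
#' @param n_partitions Number of repetitions (10 in the reference protocol).
#' @param base_seed First seed.
#' @param train_fraction Per-class training fraction.
#' @return An `eval_report`: accuracies, mean, sd, seeds, and a config
#'   fingerprint.
#' @export
repeated_evaluation <- function(epochs, config,
                                profile = optimizer_profile("desk"),
                                n_partitions = 10L, base_seed = 1L,
                                train_fraction = 0.7) {
  seeds <- base_seed + seq_len(n_partitions) - 1L
  accs <- vapply(seeds, function(s) {
    sp <- stratified_split(epochs, train_fraction, seed = s)
    tr <- normalize_epochs(sp$train)
    te <- normalize_epochs(sp$test)
    m <- train_model(tr, config, profile, seed = s)
    evaluate_model(m, te)
  }, numeric(1L))
  eval_report(accs, seeds, config)
}

#' Construct an evaluation report
#'
#' @param accuracies Per-partition accuracies in `[0, 1]`.
#' @param seeds Seeds used, one per partition.
#' @param config The `tspnet_config` evaluated (fingerprinted).
#' @return An object of class `eval_report` with `accuracies`, `mean`, `sd`
#'   (sample standard deviation), `seeds`, `config_fingerprint`.
#' @export
eval_report <- function(accuracies, seeds = seq_along(accuracies),
                        config = NULL) {
  stopifnot(all(accuracies >= 0 & accuracies <= 1))
  structure(list(
    accuracies = accuracies,
    mean = mean(accuracies),
    sd = stats::sd(accuracies),
    seeds = seeds,
    config_fingerprint = if (is.null(config)) NA_character_ else {
      paste(vapply(config, function(v) paste(format(v), collapse = ","),
                   character(1L)), collapse = "|")
    }
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d partitions: %.1f%% +/- %.1f%%\n",
              length(x$accuracies), 100 * x$mean,
              100 * ifelse(is.na(x$sd), 0, x$sd)))
  invisible(x)
}

#' Pooled-variance two-sample t-test
#'
#' Two-sided test assuming unknown but identical variances, on
#' `n_a + n_b - 2` degrees of freedom (significance threshold 0.05 in the
#' reference protocol). Degenerate zero-variance samples: equal means give
#' `t = 0, p = 1`; unequal means give `p = 0` with a warning.
#'
#' @param a,b Numeric accuracy samples (each of size >= 2).
#' @return List with `t`, `p`, `df`.
#' @export
two_sample_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 values")
  df <- length(a) + length(b) - 2L
  pooled <- ((length(a) - 1L) * stats::var(a) + (length(b) - 1L) * stats::var(b)) / df
  if (pooled == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(t = 0, p = 1, df = df))
    }
    warning("zero pooled variance with unequal means")
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, df = df))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Ablation matrix
#'
#' Evaluates the six named architecture variants — removing the temporal
#' stage, its non-residual form, removing the spatial stage, its stride-2
#' no-pooling form, removing the time-spatial head, and the full network —
#' under identical partition seeds (paired comparison), with a
#' pooled-variance t-test of each variant against the full network.
#'
#' @param epochs A balanced [epoch_set()].
#' @param base_config The full-network [tspnet_config()].
#' @param profile An [optimizer_profile()].
#' @param n_partitions Partitions per variant.
#' @param base_seed First partition seed (shared across variants).
#' @return List with `table` (data.frame: variant, mean, sd, t, p) and
#'   `reports` (named list of `eval_report`s).
#' @export
ablation_matrix <- function(epochs, base_config,
                            profile = optimizer_profile("desk"),
                            n_partitions = 5L, base_seed = 1L) {
  variants <- list(
    "TSPNet-w/o-TDFE" = list(use_tdfe = FALSE),
    "TSPNet-TDFE-NR" = list(tdfe_residual = FALSE),
    "TSPNet-w/o-SDFE" = list(use_sdfe = FALSE),
    "TSPNet-SDFE-NP" = list(sdfe_pooling_mode = "stride2"),
    "TSPNet-w/o-TSPFE" = list(use_tspfe = FALSE),
    "TSPNet" = list()
  )
  reports <- lapply(names(variants), function(vn) {
    cfg <- utils::modifyList(base_config, variants[[vn]])
    class(cfg) <- "tspnet_config"
    repeated_evaluation(epochs, cfg, profile, n_partitions, base_seed)
  })
  names(reports) <- names(variants)
  full <- reports[["TSPNet"]]
  rows <- lapply(names(variants), function(vn) {
    r <- reports[[vn]]
    if (vn == "TSPNet") {
      tt <- list(t = NA_real_, p = NA_real_)
    } else {
      tt <- two_sample_t_test(r$accuracies, full$accuracies)
    }
    data.frame(variant = vn, mean = r$mean, sd = r$sd,
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), reports = reports)
}
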