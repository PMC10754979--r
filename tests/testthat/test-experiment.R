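test_that("optimizer profiles carry the reference ADAM constants", {
  p <- optimizer_profile("paper")
  expect_equal(p$initial_learn_rate, 0.001)
  expect_equal(p$gradient_threshold, 1)
  expect_equal(p$max_epochs, 1000L)
  expect_equal(p$mini_batch_size, 64L)
  expect_equal(p$learn_rate_drop_factor, 0.1)
  expect_equal(p$learn_rate_drop_period, 500L)
  expect_equal(p$squared_gradient_decay, 0.999)
  expect_equal(p$gradient_decay, 0.9)
  expect_error(optimizer_profile("paper", learn_rate_drop_factor = 2), "drop")
})

test_that("the step-decay schedule drops the rate at the stated epochs", {
  p <- optimizer_profile("paper")
  expect_equal(learn_rate_at(p, 1L), 0.001)
  expect_equal(learn_rate_at(p, 499L), 0.001)
  expect_equal(learn_rate_at(p, 500L), 1e-4)
  expect_equal(learn_rate_at(p, 999L), 1e-4)
  expect_equal(learn_rate_at(p, 1000L), 1e-5)
})

test_that("stratified splits are balanced, disjoint, exhaustive and deterministic", {
  es <- tiny_epochs(n_per_class = 10L)
  sp <- stratified_split(es, 0.7, seed = 5L)
  expect_equal(as.integer(table(sp$train$labels)), rep(7L, 6L))
  expect_equal(as.integer(table(sp$test$labels)), rep(3L, 6L))
  expect_equal(n_trials(sp$train) + n_trials(sp$test), n_trials(es))
  sp2 <- stratified_split(es, 0.7, seed = 5L)
  expect_identical(sp$train$data, sp2$train$data)
  sp3 <- stratified_split(es, 0.7, seed = 6L)
  expect_false(identical(sp$train$data, sp3$train$data))
  # reference counts: 300 and 60 trials per class split 70/30
  expect_equal(floor(0.7 * 300), 210)
  es60 <- tiny_epochs(n_per_class = 60L, n_channels = 2L, n_samples = 8L)
  sp60 <- stratified_split(es60, 0.7, seed = 1L)
  expect_equal(as.integer(table(sp60$train$labels)), rep(42L, 6L))
  expect_equal(as.integer(table(sp60$test$labels)), rep(18L, 6L))
  # degenerate class size
  tiny <- subset_epochs(es, c(1L, which(es$labels > 0L)))
  expect_error(stratified_split(tiny), "fewer than 2")
})

test_that("evaluation scores argmax agreement with labels", {
  cfg <- tiny_model_config()
  m <- tspnet_init(cfg)
  es <- tiny_epochs(n_per_class = 3L)
  acc <- evaluate_model(m, es)
  expect_gte(acc, 0)
  expect_lte(acc, 1)
  # a head forced to predict class 0 scores exactly 1/6 on balanced labels
  m0 <- m
  m0$params[["head.W"]][] <- 0
  m0$params[["head.b"]] <- c(1, rep(0, 5))
  expect_equal(evaluate_model(m0, es), 1 / 6)
  expect_true(all(predict_classes(m0, es) == 0L))
})

test_that("a uniform random predictor scores chance level on balanced labels", {
  set.seed(60)
  n <- 3000L
  labels <- rep(0:5, each = n / 6L)
  preds <- sample(0:5, n, replace = TRUE)
  acc <- mean(preds == labels)
  ci <- qbinom(c(0.025, 0.975), n, 1 / 6) / n
  expect_gte(acc, ci[1L])
  expect_lte(acc, ci[2L])
})

test_that("evaluation reports aggregate accuracies with sample SD", {
  r <- eval_report(c(0.4, 0.6), seeds = c(1L, 2L))
  expect_equal(r$mean, 0.5)
  expect_equal(r$sd, sd(c(0.4, 0.6)), tolerance = 1e-12)
  expect_equal(r$sd, 0.1414, tolerance = 1e-3)
  r2 <- eval_report(rep(0.8, 4))
  expect_equal(r2$sd, 0)
  expect_length(r2$seeds, 4L)
  expect_error(eval_report(c(0.5, 1.2)), "accuracies")
})

test_that("pooled-variance t-test matches its hand-evaluated form and edge cases", {
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  r <- two_sample_t_test(a, b)
  # hand evaluation of the pooled formula
  spool <- sqrt(((3 * var(a) + 3 * var(b)) / 6) * (1 / 4 + 1 / 4))
  expect_equal(r$t, (mean(a) - mean(b)) / spool, tolerance = 1e-12)
  expect_equal(r$t, -2.1909, tolerance = 1e-4)
  expect_equal(r$df, 6)
  expect_equal(r$p, 0.070988, tolerance = 1e-4)
  # symmetry
  r2 <- two_sample_t_test(b, a)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  # degenerate: identical constant samples
  expect_equal(two_sample_t_test(c(1, 1), c(1, 1)), list(t = 0, p = 1, df = 2))
  expect_warning(rz <- two_sample_t_test(c(1, 1), c(2, 2)), "zero pooled")
  expect_equal(rz$p, 0)
  expect_error(two_sample_t_test(1, c(1, 2)), ">= 2")
})

test_that("training reduces the loss and is reproducible given a seed", {
  es <- desk_test_data(effect_size = 3, seed = 61L, trials_per_class = 8L)
  tr <- normalize_epochs(es)
  cfg <- desk_test_model_config()
  prof <- optimizer_profile("desk", max_epochs = 4L, mini_batch_size = 16L)
  m <- train_model(tr, cfg, prof, seed = 3L)
  expect_length(m$loss_history, 4L)
  expect_lt(m$loss_history[4L], m$loss_history[1L])
  m2 <- train_model(tr, cfg, prof, seed = 3L)
  expect_identical(m$params, m2$params)
  expect_identical(predict_proba(m, tr), predict_proba(m2, tr))
})

test_that("a small strong-effect set can be memorized", {
  es <- desk_test_data(effect_size = 3, seed = 62L, trials_per_class = 6L)
  tr <- normalize_epochs(es)
  cfg <- desk_test_model_config()
  prof <- optimizer_profile("desk", max_epochs = 60L, mini_batch_size = 12L,
                            initial_learn_rate = 0.002)
  m <- train_model(tr, cfg, prof, seed = 4L)
  expect_equal(evaluate_model(m, tr), 1.0)
})

test_that("the ablation matrix pairs all six named variants on shared seeds", {
  # verified on a miniature problem so each variant trains in seconds
  es <- desk_test_data(effect_size = 3, seed = 63L, trials_per_class = 5L,
                       n_samples = 32L)
  cfg <- desk_test_model_config(n_samples = 32L)
  prof <- optimizer_profile("desk", max_epochs = 2L, mini_batch_size = 12L)
  ab <- ablation_matrix(es, cfg, prof, n_partitions = 2L, base_seed = 9L)
  expect_equal(ab$table$variant,
               c("TSPNet-w/o-TDFE", "TSPNet-TDFE-NR", "TSPNet-w/o-SDFE",
                 "TSPNet-SDFE-NP", "TSPNet-w/o-TSPFE", "TSPNet"))
  expect_equal(nrow(ab$table), 6L)
  for (r in ab$reports) expect_equal(r$seeds, c(9L, 10L))
  expect_true(all(is.na(ab$table[ab$table$variant == "TSPNet", c("t", "p")])))
  expect_true(all(ab$table$mean >= 0 & ab$table$mean <= 1))
})

test_that("head width halves when the time-spatial head is ablated", {
  cfg_full <- desk_test_model_config()
  cfg_wo <- desk_test_model_config(use_tspfe = FALSE)
  expect_equal(tspnet_shapes(cfg_full)$head_in,
               2L * tspnet_shapes(cfg_wo)$head_in)
  m_full <- tspnet_init(cfg_full)
  m_wo <- tspnet_init(cfg_wo)
  expect_equal(ncol(m_full$params[["head.W"]]),
               2L * ncol(m_wo$params[["head.W"]]))
})
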