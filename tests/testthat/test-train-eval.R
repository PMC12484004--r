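# Training harness: splits, schedule, clipping, early stopping,
# determinism, metrics, ablation plumbing.

test_that("patient splits have exact 80-10-10 sizes and partition the cohort", {
  patients <- sprintf("P%03d", 1:100)
  sp <- split_dataset(patients, seed = 42)
  expect_length(sp$train, 80)
  expect_length(sp$val, 10)
  expect_length(sp$test, 10)
  expect_setequal(c(sp$train, sp$val, sp$test), patients)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_dataset(patients, seed = 42))
  expect_false(identical(sp$train, split_dataset(patients, seed = 43)$train))
  expect_error(split_dataset(patients[1:2]), "fewer patients")
})

test_that("stratified splits keep class balance within one patient", {
  patients <- sprintf("P%03d", 1:100)
  labels <- rep(c(0, 1), each = 50)
  sp <- split_dataset(patients, seed = 7, labels = labels)
  lab <- setNames(labels, patients)
  expect_lte(abs(sum(lab[sp$train] == 1) - 40), 1)
  expect_lte(abs(sum(lab[sp$test] == 1) - 5), 1)
})

test_that("the cosine schedule starts at the base rate and decays monotonically", {
  lrs <- vapply(1:100, amfn:::cosine_lr, numeric(1), epochs = 100,
                lr = 0.001, eta_min = 0)
  expect_equal(lrs[1], 0.001)
  expect_true(all(diff(lrs) < 0))
  expect_lt(lrs[100], 1e-6 + 0.001 * 0.5 * (1 + cos(pi * 99 / 100)))
})

test_that("gradient trees are clipped to the global norm ceiling", {
  g <- list(a = matrix(3, 2, 2), b = list(c = rep(4, 5)))
  norm <- sqrt(amfn:::tree_sumsq(g))
  clipped <- amfn:::tree_scale(g, 1 / norm)
  expect_equal(sqrt(amfn:::tree_sumsq(clipped)), 1, tolerance = 1e-12)
  expect_equal(clipped$a, g$a / norm)
})

test_that("training is reproducible and improves on the initial model", {
  prep <- tiny_prep(tiny_dataset(n_patients = 12))
  run_once <- function() {
    model <- tiny_model()
    train_amfn(model, prep$train, prep$val,
               train_config(epochs = 4L, batch_size = 16L, seed = 2))
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$model$params, b$model$params)
  expect_identical(a$history, b$history)
  expect_equal(nrow(a$history), 4)
  expect_true(all(is.finite(a$history$train_loss)))
  expect_lt(a$history$train_loss[4], a$history$train_loss[1])
})

test_that("early stopping halts after the configured patience and restores the best epoch", {
  prep <- tiny_prep(tiny_dataset(n_patients = 12))
  model <- tiny_model()
  fit <- train_amfn(model, prep$train, prep$val,
                    train_config(epochs = 40L, batch_size = 16L,
                                 patience = 3L, seed = 2))
  h <- fit$history
  best <- attr(fit$model, "best_epoch")
  expect_equal(best, which.min(h$val_loss)) # which.min takes the earliest tie
  expect_lte(nrow(h), 40)
  if (nrow(h) < 40) expect_equal(nrow(h), best + 3)
})

test_that("perfect predictions give the identity metric values", {
  y <- c(1.5, -2, 3, 0.5)
  m <- regression_metrics(y, y)
  expect_equal(m$rmse, 0)
  expect_equal(m$mae, 0)
  expect_equal(m$r_squared, 1)
  expect_equal(m$mape, 0)
})

test_that("the mean predictor has zero R-squared", {
  y <- c(1, 2, 3, 7)
  m <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(m$r_squared, 0)
})

test_that("hand-computed toy metrics are reproduced", {
  m <- regression_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m$mae, 2 / 3)
  expect_equal(m$rmse, sqrt(2 / 3))
})

test_that("rmse dominates mae on random evaluations", {
  set.seed(17)
  for (rep in 1:20) {
    y <- rnorm(50); yhat <- rnorm(50)
    m <- regression_metrics(y, yhat)
    expect_gte(m$rmse, m$mae)
    expect_gte(m$mape, 0)
    expect_lte(m$r_squared, 1)
  }
})

test_that("constant response yields a missing R-squared with a warning", {
  expect_warning(m <- regression_metrics(rep(2, 5), rnorm(5)), "constant")
  expect_true(is.na(m$r_squared))
})

test_that("near-zero targets are flagged in the MAPE denominator", {
  m <- regression_metrics(c(0, 1), c(1, 1))
  expect_equal(m$mape_flagged, 1)
  expect_equal(m$mape, mean(c(1 / 1e-8, 0)))
})

test_that("classification metrics follow the 0.5 threshold", {
  y <- c(1, 1, 0, 0, 1)
  p <- c(0.9, 0.4, 0.2, 0.6, 0.5)
  m <- classification_metrics(y, p)
  expect_equal(m$accuracy, 3 / 5)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
})

test_that("evaluate rejects empty splits and reports gate and fusion weights", {
  prep <- tiny_prep()
  model <- tiny_model()
  # a one-patient test split has a constant response, so R-squared warns
  ev <- suppressWarnings(evaluate(model, prep$test))
  expect_s3_class(ev, "metrics_report")
  expect_length(ev$gamma_mean, 3)
  expect_equal(sum(ev$beta_mean), 1, tolerance = 1e-6)
  empty <- amfn:::subset_windows(prep$test, integer(0))
  expect_error(evaluate(model, empty), "empty")
})

test_that("ablation variants map to the advertised model arguments", {
  expect_equal(amfn:::variant_model_args("no_feature_extraction")$encoder_type,
               "mean")
  expect_equal(amfn:::variant_model_args("no_cross_modal_attention")$ablate,
               "attention")
  expect_equal(amfn:::variant_model_args("no_adaptive_feature_selection")$ablate,
               "gating")
  expect_length(amfn:::variant_model_args("full"), 0)
  expect_error(amfn:::variant_model_args("bogus"), "unknown ablation")
})

test_that("the ablation runner produces a variant-by-metric table over seeds", {
  prep <- tiny_prep(tiny_dataset(n_patients = 12))
  tab <- suppressWarnings(run_ablation(
    prep, variants = c("full", "no_adaptive_feature_selection"),
    seeds = 1:2,
    model_args = list(M = 3, channels = c(2, 3, 2),
                      win = 32L, d = 4L, dropout = 0),
    train_args = list(epochs = 2L, batch_size = 32L)))
  expect_equal(tab$variant, c("full", "no_adaptive_feature_selection"))
  expect_true(all(c("rmse_mean", "rmse_sd", "mae_mean") %in% names(tab)))
  raw <- attr(tab, "per_seed")
  expect_equal(nrow(raw), 4)
  expect_error(run_ablation(prep, "nope", seeds = 1:2), "unknown ablation")
  expect_error(run_ablation(prep, "full", seeds = 1), "length")
})

test_that("cross-validation partitions patients across folds", {
  ds <- tiny_dataset(n_patients = 10)
  cv <- cross_validate(ds, k = 2, model_args = list(M = 3,
                                                    channels = c(2, 3, 2),
                                                    win = 32L, d = 4L,
                                                    dropout = 0),
                       train_args = list(epochs = 2L, batch_size = 32L),
                       preprocess_args = list(win = 32L, stride = 16L),
                       seed = 3)
  expect_equal(nrow(cv), 2)
  expect_true(all(c("rmse", "mae") %in% names(cv)))
  expect_s3_class(attr(cv, "summary"), "data.frame")
})
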