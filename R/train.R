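# Training harness: patient-level splits, Adam with cosine-annealed learning
# rate, global gradient-norm clipping, early stopping on validation loss
# (restoring the earliest best checkpoint on ties), evaluation metrics, and
# the ablation matrix.

#' Split patients into train/validation/test sets
#'
#' Partitions at the patient level so no window of one patient can appear in
#' two splits. Deterministic given the seed; split sizes are within one
#' patient of the exact ratios. With `labels` supplied, the split is
#' stratified within label groups.
#'
#' @param patients character vector of patient ids.
#' @param ratios length-3 positive numeric summing to 1 (default 80-10-10).
#' @param seed integer seed.
#' @param labels optional vector (named by patient or aligned with
#'   `patients`) used for stratification.
#' @return list with character vectors `train`, `val`, `test` forming a
#'   partition of `patients`.
#' @export
split_dataset <- function(patients, ratios = c(0.8, 0.1, 0.1), seed = 1L,
                          labels = NULL) {
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  if (abs(sum(ratios) - 1) > 1e-8) stop_amfn("ratios must sum to 1")
  if (length(patients) < 3L) stop_amfn("fewer patients than splits")
  one_group <- function(ids, seed) {
    perm <- with_seed(seed, sample(ids))
    n <- length(perm)
    n_tr <- round(ratios[1L] * n)
    n_va <- round(ratios[2L] * n)
    n_tr <- min(n_tr, n - 2L); n_va <- max(1L, min(n_va, n - n_tr - 1L))
    list(train = perm[seq_len(n_tr)],
         val = perm[n_tr + seq_len(n_va)],
         test = perm[(n_tr + n_va + 1L):n])
  }
  if (is.null(labels)) return(one_group(patients, seed))
  if (!is.null(names(labels))) labels <- labels[patients]
  groups <- split(patients, labels)
  parts <- lapply(seq_along(groups), function(k) {
    one_group(groups[[k]], derive_seed(seed, k))
  })
  list(train = unlist(lapply(parts, `[[`, "train"), use.names = FALSE),
       val = unlist(lapply(parts, `[[`, "val"), use.names = FALSE),
       test = unlist(lapply(parts, `[[`, "test"), use.names = FALSE))
}

#' Training configuration
#'
#' Defaults: Adam at learning rate 0.001 with
#' cosine annealing over the epoch budget, batch size 256, 100 epochs,
#' weight decay 1e-5, gradient-norm clipping at 1.0, early stopping with
#' patience 10 on validation loss.
#'
#' @param lr initial learning rate.
#' @param epochs epoch budget (the annealing horizon).
#' @param batch_size minibatch size.
#' @param weight_decay L2 penalty coefficient added to gradients.
#' @param grad_clip global gradient-norm ceiling.
#' @param patience epochs without validation improvement before stopping.
#' @param eta_min annealing floor of the learning rate.
#' @param seed integer seed controlling shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 0.001, epochs = 100L, batch_size = 256L,
                         weight_decay = 1e-5, grad_clip = 1.0,
                         patience = 10L, eta_min = 0, seed = 1L,
                         verbose = FALSE) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, grad_clip = grad_clip,
                 patience = as.integer(patience), eta_min = eta_min,
                 seed = as.integer(seed), verbose = verbose),
            class = "train_config")
}

cosine_lr <- function(epoch, epochs, lr, eta_min = 0) {
  eta_min + 0.5 * (lr - eta_min) * (1 + cos(pi * (epoch - 1) / epochs))
}

# ---- gradient-tree utilities ----------------------------------------------

tree_sumsq <- function(g) {
  if (is.list(g)) return(sum(vapply(g, tree_sumsq, numeric(1))))
  if (is.numeric(g)) return(sum(g^2))
  0
}

tree_scale <- function(g, s) {
  if (is.list(g)) return(lapply(g, tree_scale, s = s))
  if (is.numeric(g)) return(g * s)
  g
}

# Walks the gradient tree (a subtree of the parameter tree) and applies Adam
# in place, with L2 weight decay folded into the gradient.
adam_update <- function(params, grads, state, lr, wd, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state)) state <- list(m = NULL, v = NULL)
  step <- function(p, g, m, v) {
    g <- g + wd * p
    m <- if (is.null(m)) (1 - beta1) * g else beta1 * m + (1 - beta1) * g
    v <- if (is.null(v)) (1 - beta2) * g^2 else beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(g)) {
      keys <- if (!is.null(names(g))) names(g) else seq_along(g)
      m <- m %||% vector("list", length(g))
      v <- v %||% vector("list", length(g))
      if (!is.null(names(g))) { names(m) <- keys; names(v) <- keys }
      for (k in keys) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else {
      step(p, g, m, v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v))
}

views_subset <- function(views, idx) {
  list(X = lapply(views$X, function(x) x[idx, , drop = FALSE]),
       mask = lapply(views$mask, function(m) m[idx, , drop = FALSE]),
       present = views$present[idx, , drop = FALSE],
       y = views$y[idx])
}

eval_loss <- function(model, views, chunk = 1024L) {
  n <- nrow(views$present)
  tot <- 0
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    fw <- model_forward(model, views_subset(views, idx), train = FALSE)
    tot <- tot + fw$loss$total * length(idx)
  }
  tot / n
}

#' Train an adaptive multimodal fusion model
#'
#' Minimizes the composite objective with Adam (cosine-annealed learning
#' rate, gradient-norm clipping, L2 weight decay). Embedding-standardization
#' statistics are fitted once on the training split before the first epoch
#' and stay frozen for the whole run. Early stopping monitors the validation
#' loss with the configured patience and restores the earliest best
#' checkpoint.
#'
#' @param model an `amfn_model` from [init_model()].
#' @param train_batch,val_batch `window_batch`es from
#'   [preprocess_dataset()].
#' @param cfg a [train_config()].
#' @return list with the fitted `model` and a `history` data.frame
#'   (epoch, lr, train_loss, val_loss).
#' @export
train_amfn <- function(model, train_batch, val_batch, cfg = train_config()) {
  vt <- batch_to_views(train_batch)
  vv <- batch_to_views(val_batch)
  n <- nrow(vt$present)
  state <- NULL
  tstep <- 0L
  best <- list(loss = Inf, params = model$params, stats = model$emb_stats,
               epoch = 0L)
  waited <- 0L
  hist <- data.frame(epoch = integer(0), lr = numeric(0),
                     train_loss = numeric(0), val_loss = numeric(0))
  # Embedding-standardization statistics are fitted once on the training
  # split and frozen for the whole run: refitting them as the encoders move
  # would rescale every downstream layer's inputs each epoch and visibly
  # stalls convergence.
  model <- refit_emb_stats(model, vt)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_lr(epoch, cfg$epochs, cfg$lr, cfg$eta_min)
    perm <- with_seed(derive_seed(cfg$seed, epoch), sample.int(n))
    batch_losses <- numeric(0)
    set.seed(derive_seed(cfg$seed, 100000L + epoch)) # dropout stream
    for (s in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[s:min(n, s + cfg$batch_size - 1L)]
      vb <- views_subset(vt, idx)
      fw <- model_forward(model, vb, train = TRUE)
      for (comp in c("task", "rec", "align")) {
        if (!is.finite(fw$loss[[comp]])) {
          stop_amfn(sprintf("non-finite %s loss at epoch %d", comp, epoch))
        }
      }
      grads <- model_backward(model, vb, fw)
      gnorm <- sqrt(tree_sumsq(grads))
      if (is.finite(gnorm) && gnorm > cfg$grad_clip) {
        grads <- tree_scale(grads, cfg$grad_clip / gnorm)
      }
      tstep <- tstep + 1L
      upd <- adam_update(model$params, grads, state, lr, cfg$weight_decay,
                         tstep)
      model$params <- upd$params
      state <- upd$state
      batch_losses <- c(batch_losses, fw$loss$total)
    }
    val_loss <- eval_loss(model, vv)
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = mean(batch_losses),
                                   val_loss = val_loss))
    if (cfg$verbose) {
      message(sprintf("epoch %3d lr %.5f train %.4f val %.4f",
                      epoch, lr, mean(batch_losses), val_loss))
    }
    if (val_loss < best$loss) { # strict: ties keep the earliest best epoch
      best <- list(loss = val_loss, params = model$params,
                   stats = model$emb_stats, epoch = epoch)
      waited <- 0L
    } else {
      waited <- waited + 1L
      if (waited >= cfg$patience) break
    }
  }
  model$params <- best$params
  model$emb_stats <- best$stats
  attr(model, "best_epoch") <- best$epoch
  list(model = model, history = hist)
}

#' Predict from a fitted model
#'
#' @param object an `amfn_model`.
#' @param batch a `window_batch`.
#' @param ... unused.
#' @return list with `yhat` (and `prob` for binary tasks), `gamma` and
#'   `beta` matrices (windows x modalities).
#' @export
predict.amfn_model <- function(object, batch, ...) {
  views <- batch_to_views(batch)
  n <- nrow(views$present)
  out <- list(yhat = numeric(n), prob = NULL,
              gamma = matrix(0, n, object$cfg$M),
              beta = matrix(0, n, object$cfg$M))
  if (object$cfg$task == "binary") out$prob <- numeric(n)
  for (s in seq(1L, n, by = 1024L)) {
    idx <- s:min(n, s + 1023L)
    fw <- model_forward(object, views_subset(views, idx), train = FALSE,
                        compute_loss = FALSE)
    out$yhat[idx] <- fw$yhat
    if (!is.null(out$prob)) out$prob[idx] <- fw$prob
    out$gamma[idx, ] <- fw$gamma
    out$beta[idx, ] <- fw$beta
  }
  out
}

#' Evaluate a fitted model on a window batch
#'
#' Regression reports RMSE, MAE, R-squared (against the split-mean
#' baseline) and MAPE (`|yhat - y| / max(|y|, 1e-8)`, rows at the epsilon
#' floor flagged); classification reports accuracy, precision, recall and
#' F1 at threshold 0.5. Mean per-modality gate and fusion weights are
#' returned alongside.
#'
#' @param model fitted `amfn_model`.
#' @param batch a nonempty `window_batch`.
#' @return list of class `metrics_report` with `metrics`, `gamma_mean`,
#'   `beta_mean`, `n`.
#' @export
evaluate <- function(model, batch) {
  if (n_windows(batch) == 0L) stop_amfn("evaluate: empty split")
  pr <- predict(model, batch)
  y <- batch$labels
  metrics <- if (model$cfg$task == "regression") {
    regression_metrics(y, pr$yhat)
  } else {
    classification_metrics(y, pr$prob)
  }
  structure(list(metrics = metrics,
                 gamma_mean = colMeans(pr$gamma),
                 beta_mean = colMeans(pr$beta),
                 n = n_windows(batch)),
            class = "metrics_report")
}

#' Regression error metrics
#'
#' @param y,yhat observed and predicted values.
#' @return named list: `rmse`, `mae`, `r_squared` (NA with a warning when y
#'   is constant), `mape`, `mape_flagged` (count of rows where `|y|` hit the
#'   1e-8 floor).
#' @export
regression_metrics <- function(y, yhat) {
  err <- yhat - y
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst < 1e-12) {
    warning("constant response: R-squared undefined")
    NA_real_
  } else 1 - sum(err^2) / sst
  denom <- pmax(abs(y), 1e-8)
  list(rmse = rmse, mae = mae, r_squared = r2,
       mape = mean(abs(err) / denom),
       mape_flagged = sum(abs(y) < 1e-8))
}

#' Binary classification metrics at threshold 0.5
#'
#' @param y 0/1 labels.
#' @param prob predicted class-1 probabilities.
#' @return named list: `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(y, prob) {
  pred <- as.integer(prob >= 0.5)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.finite(prec) && is.finite(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  list(accuracy = mean(pred == y), precision = prec, recall = rec, f1 = f1)
}

ablation_variants <- c("full", "no_feature_extraction",
                       "no_cross_modal_attention",
                       "no_adaptive_feature_selection")

variant_model_args <- function(variant) {
  switch(variant,
         full = list(),
         no_feature_extraction = list(encoder_type = "mean"),
         no_cross_modal_attention = list(ablate = "attention"),
         no_adaptive_feature_selection = list(ablate = "gating"),
         stop_amfn(sprintf("unknown ablation variant '%s'", variant)))
}

#' Run the ablation matrix
#'
#' Trains and evaluates the model variants obtained by replacing one named
#' mechanism with an identity/constant: `no_cross_modal_attention` sets the
#' attended embeddings to the embeddings themselves, `no_adaptive_feature_selection`
#' fixes every gate at 1, `no_feature_extraction` swaps each encoder for a
#' channel-mean + linear projection. Everything else is held fixed.
#'
#' @param prep output of [preprocess_dataset()].
#' @param variants subset of
#'   `c("full", "no_feature_extraction", "no_cross_modal_attention",
#'   "no_adaptive_feature_selection")`.
#' @param seeds integer vector (>= 2) of training seeds.
#' @param model_args list of arguments forwarded to [init_model()].
#' @param train_args list of arguments forwarded to [train_config()].
#' @return data.frame: one row per variant x metric with mean and sd over
#'   seeds, plus a `per_seed` attribute holding raw values.
#' @export
run_ablation <- function(prep, variants = ablation_variants, seeds = 1:2,
                         model_args = list(), train_args = list()) {
  stopifnot(length(seeds) >= 2L)
  bad <- setdiff(variants, ablation_variants)
  if (length(bad)) stop_amfn(sprintf("unknown ablation variant '%s'", bad[1L]))
  per_seed <- list()
  for (variant in variants) {
    for (seed in seeds) {
      args <- utils::modifyList(model_args, variant_model_args(variant))
      args$seed <- seed
      model <- do.call(init_model, args)
      tc <- do.call(train_config, utils::modifyList(train_args,
                                                    list(seed = seed)))
      fit <- train_amfn(model, prep$train, prep$val, tc)
      ev <- evaluate(fit$model, prep$test)
      per_seed[[length(per_seed) + 1L]] <-
        c(list(variant = variant, seed = seed), ev$metrics)
    }
  }
  raw <- do.call(rbind, lapply(per_seed, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  metric_cols <- setdiff(names(raw), c("variant", "seed"))
  agg <- do.call(rbind, lapply(split(raw, raw$variant), function(df) {
    row <- data.frame(variant = df$variant[1L])
    for (mc in metric_cols) {
      row[[paste0(mc, "_mean")]] <- mean(df[[mc]])
      row[[paste0(mc, "_sd")]] <- stats::sd(df[[mc]])
    }
    row
  }))
  agg <- agg[match(variants, agg$variant), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "per_seed") <- raw
  agg
}

#' Patient-level k-fold cross-validation
#'
#' Outer loop over patient folds: each fold serves once as the test set
#' while the remainder is split into train/validation, the model is trained
#' from scratch, and test metrics are collected.
#'
#' @param dataset an `amfn_dataset`.
#' @param k number of folds (default 5).
#' @param model_args,train_args,preprocess_args argument lists for
#'   [init_model()], [train_config()], [preprocess_dataset()].
#' @param seed integer seed for fold assignment.
#' @return data.frame of per-fold metrics with a final mean/sd summary
#'   attribute.
#' @export
cross_validate <- function(dataset, k = 5L, model_args = list(),
                           train_args = list(), preprocess_args = list(),
                           seed = 1L) {
  patients <- dataset$labels$patient_id
  folds <- with_seed(seed, split(sample(patients),
                                 rep_len(seq_len(k), length(patients))))
  rows <- list()
  for (f in seq_len(k)) {
    test_ids <- folds[[f]]
    rest <- setdiff(patients, test_ids)
    n_val <- max(1L, round(0.1 * length(rest)))
    val_ids <- with_seed(derive_seed(seed, f), sample(rest, n_val))
    split <- list(train = setdiff(rest, val_ids), val = val_ids,
                  test = test_ids)
    prep <- do.call(preprocess_dataset,
                    c(list(dataset = dataset, split = split),
                      preprocess_args))
    args <- model_args
    args$seed <- derive_seed(seed, 100L + f)
    model <- do.call(init_model, args)
    tc <- do.call(train_config,
                  utils::modifyList(train_args,
                                    list(seed = derive_seed(seed, 200L + f))))
    fit <- train_amfn(model, prep$train, prep$val, tc)
    ev <- evaluate(fit$model, prep$test)
    rows[[f]] <- as.data.frame(c(list(fold = f), ev$metrics))
  }
  out <- do.call(rbind, rows)
  metric_cols <- setdiff(names(out), "fold")
  attr(out, "summary") <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(mc) mean(out[[mc]]), numeric(1)),
    sd = vapply(metric_cols, function(mc) stats::sd(out[[mc]]), numeric(1))
  )
  out
}
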