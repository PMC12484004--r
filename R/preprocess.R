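# ICU-style preprocessing pipeline. Fixed stage order:
#   align -> segment -> filter -> impute -> z-score (statistics fit on the
# training split only). The order is recorded in every run manifest.

#' Resample a modality record onto a uniform time grid
#'
#' Linearly interpolates each channel onto the uniform grid spanning the
#' record. Interpolation only bridges observed neighbours at most `max_gap`
#' time units apart; cells inside longer gaps, and cells outside the observed
#' span, stay missing so that downstream imputation (not interpolation)
#' decides how to fill them. Grid points that coincide with an observed
#' timestamp always keep the observed value.
#'
#' @param record a `modality_record`.
#' @param grid_step grid spacing in the record's time units (> 0).
#' @param max_gap largest neighbour separation bridged by interpolation, in
#'   time units. Default 10.
#' @param t_range optional `c(t0, t1)` span for the grid, e.g. the common
#'   span of all of a patient's modalities; defaults to the record's own.
#' @return a `modality_record` on the uniform grid, `NA` where unresolved.
#'   A channel with fewer than 2 observations is left entirely missing with a
#'   warning.
#' @export
align_resample <- function(record, grid_step = 1, max_gap = 10,
                           t_range = NULL) {
  stopifnot(inherits(record, "modality_record"))
  if (grid_step <= 0) stop_amfn("grid_step must be positive")
  t0 <- if (is.null(t_range)) min(record$timestamps) else t_range[1L]
  t1 <- if (is.null(t_range)) max(record$timestamps) else t_range[2L]
  grid <- seq(t0, t1, by = grid_step)
  C <- length(record$channels)
  out <- matrix(NA_real_, C, length(grid))
  for (c in seq_len(C)) {
    obs <- which(is.finite(record$values[c, ]))
    if (length(obs) < 2L) {
      warning(sprintf("channel '%s' of patient %s has < 2 observations; left missing",
                      record$channels[c], record$patient_id))
      next
    }
    tt <- record$timestamps[obs]
    vv <- record$values[c, obs]
    y <- stats::approx(tt, vv, xout = grid, method = "linear", rule = 1)$y
    # void interpolation across gaps wider than max_gap, except at grid
    # points that hit an observed timestamp exactly
    iv <- findInterval(grid, tt)
    inside <- iv >= 1L & iv < length(tt)
    wide <- inside & (tt[pmin(iv + 1L, length(tt))] - tt[pmax(iv, 1L)]) > max_gap
    on_obs <- grid %in% tt
    y[wide & !on_obs] <- NA_real_
    out[c, ] <- y
  }
  modality_record(record$patient_id, record$modality, record$channels, grid, out)
}

#' Segment a series into overlapping fixed-length windows
#'
#' Returns the half-open, 0-based index ranges `[start, start + win)` with
#' starts `0, stride, 2 * stride, ...` while the full window fits; incomplete
#' tail windows are dropped. With the defaults (256-step windows, stride 128)
#' consecutive windows overlap by half.
#'
#' @param T series length in steps.
#' @param win window length (default 256).
#' @param stride hop between window starts (default 128).
#' @return data.frame with columns `start`, `end` (0-based, half-open); zero
#'   rows when `T < win`.
#' @export
#' @examples
#' segment_windows(1000) # 6 windows: starts 0, 128, ..., 640
segment_windows <- function(T, win = 256L, stride = 128L) {
  stopifnot(win >= 1L, stride >= 1L)
  if (T < win) return(data.frame(start = integer(0), end = integer(0)))
  starts <- seq.int(0L, T - win, by = stride)
  data.frame(start = as.integer(starts), end = as.integer(starts + win))
}

#' Assemble aligned records into a multimodal window batch
#'
#' Cuts every patient's aligned modality records into overlapping windows and
#' stacks them into per-modality arrays. All modalities of one patient must
#' already live on a common integer grid (see [align_resample()]).
#'
#' @param records list (patients) of lists of aligned `modality_record`s.
#' @param labels data.frame with `patient_id`, `label`.
#' @param win,stride window length and hop, in steps.
#' @return object of class `window_batch`: per-modality value arrays
#'   `n x C_m x win` (with `NA` at missing cells until imputation), congruent
#'   logical observation masks, `modality_present` (n x M), label vector,
#'   `patient_id` and `window_start` vectors.
#' @export
build_window_batch <- function(records, labels, win = 256L, stride = 128L) {
  M <- length(records[[1L]])
  modal_names <- names(records[[1L]])
  lab_map <- stats::setNames(labels$label, labels$patient_id)

  rows <- list(); pid <- character(0); wstart <- integer(0)
  for (p in seq_along(records)) {
    lens <- vapply(records[[p]], function(r) length(r$timestamps), integer(1))
    if (length(unique(lens)) != 1L) {
      stop_amfn(sprintf(
        "patient %s: modalities are on different time grids; run align_resample first",
        records[[p]][[1L]]$patient_id))
    }
    T <- length(records[[p]][[1L]]$timestamps)
    seg <- segment_windows(T, win, stride)
    if (nrow(seg) == 0L) next
    for (w in seq_len(nrow(seg))) {
      rows[[length(rows) + 1L]] <- c(p, seg$start[w])
      pid <- c(pid, records[[p]][[1L]]$patient_id)
      wstart <- c(wstart, seg$start[w])
    }
  }
  n <- length(rows)
  values <- masks <- vector("list", M)
  names(values) <- names(masks) <- modal_names
  present <- matrix(1L, n, M, dimnames = list(NULL, modal_names))
  for (m in seq_len(M)) {
    C <- length(records[[1L]][[m]]$channels)
    v <- array(NA_real_, c(n, C, win))
    for (i in seq_len(n)) {
      p <- rows[[i]][1L]; s <- rows[[i]][2L]
      v[i, , ] <- records[[p]][[m]]$values[, (s + 1L):(s + win), drop = FALSE]
    }
    msk <- is.finite(v)
    present[, m] <- as.integer(apply(msk, 1L, any))
    values[[m]] <- v
    masks[[m]] <- msk
  }
  structure(list(
    values = values, masks = masks, modality_present = present,
    labels = unname(lab_map[pid]), patient_id = pid, window_start = wstart,
    channels = lapply(records[[1L]], function(r) r$channels),
    win = as.integer(win)
  ), class = "window_batch")
}

n_windows <- function(batch) length(batch$labels)

# Pooled missing fraction per window: every cell of every modality/channel/
# step counts once, unweighted.
window_missing_fraction <- function(batch) {
  n <- n_windows(batch)
  miss <- total <- numeric(n)
  for (m in seq_along(batch$masks)) {
    msk <- batch$masks[[m]]
    cells <- dim(msk)[2L] * dim(msk)[3L]
    miss <- miss + (cells - apply(msk, 1L, sum))
    total <- total + cells
  }
  miss / total
}

#' Drop windows exceeding the missingness threshold
#'
#' A window is removed iff its pooled missing-cell fraction across all
#' modalities, channels and steps (computed before imputation) is strictly
#' greater than `max_missing`; a window at exactly the threshold is retained.
#'
#' @param batch a `window_batch`.
#' @param max_missing threshold fraction, default 0.4.
#' @return the filtered `window_batch`, with attributes `n_dropped` and
#'   `n_retained`.
#' @export
filter_windows <- function(batch, max_missing = 0.4) {
  frac <- window_missing_fraction(batch)
  keep <- frac <= max_missing
  out <- subset_windows(batch, which(keep))
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "n_retained") <- sum(keep)
  out
}

subset_windows <- function(batch, idx) {
  batch$values <- lapply(batch$values, function(v) v[idx, , , drop = FALSE])
  batch$masks <- lapply(batch$masks, function(m) m[idx, , , drop = FALSE])
  batch$modality_present <- batch$modality_present[idx, , drop = FALSE]
  batch$labels <- batch$labels[idx]
  batch$patient_id <- batch$patient_id[idx]
  batch$window_start <- batch$window_start[idx]
  batch
}

#' Two-stage imputation of a single channel series
#'
#' Gaps of length at most `long_gap` are filled by carrying the last observed
#' value forward; longer gaps, and leading gaps with no prior observation,
#' are filled with the channel's training-set mean.
#'
#' @param x numeric vector with `NA` at missing positions.
#' @param long_gap longest gap still forward-filled (>= 1).
#' @param channel_mean training-set mean used for long/leading gaps.
#' @return complete numeric vector (no `NA`).
#' @export
#' @examples
#' impute_two_stage(c(1, NA, NA, 4), long_gap = 2, channel_mean = 10)
#' impute_two_stage(c(1, NA, NA, NA, 4), long_gap = 2, channel_mean = 10)
impute_two_stage <- function(x, long_gap = 60L, channel_mean = 0) {
  stopifnot(long_gap >= 1L)
  miss <- !is.finite(x)
  if (!any(miss)) return(x)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    s <- starts[k]; e <- ends[k]; len <- r$lengths[k]
    if (s == 1L || len > long_gap) {
      x[s:e] <- channel_mean
    } else {
      x[s:e] <- x[s - 1L]
    }
  }
  x
}

#' Impute every channel of a window batch
#'
#' Applies [impute_two_stage()] within each window and channel, using the
#' training-set channel means in `stats$channel_means`. Windows in which a
#' modality is entirely absent keep `modality_present = 0` and are filled with
#' the channel mean (zero after z-scoring), so the encoder can mask them.
#' Observation masks are preserved unchanged for later loss masking.
#'
#' @param batch a `window_batch`.
#' @param stats result of [fit_channel_stats()] on the training split.
#' @param long_gap longest forward-fillable gap, in steps.
#' @return the batch with no missing values.
#' @export
impute_batch <- function(batch, stats, long_gap = 60L) {
  for (m in seq_along(batch$values)) {
    mu <- stats$channel_means[[m]]
    v <- batch$values[[m]]
    for (c in seq_len(dim(v)[2L])) {
      for (i in seq_len(dim(v)[1L])) {
        v[i, c, ] <- impute_two_stage(v[i, c, ], long_gap, mu[c])
      }
    }
    batch$values[[m]] <- v
  }
  batch
}

#' Fit per-channel training statistics
#'
#' Computes, on the training split only, the observed-cell mean of every
#' modality channel (used by long-gap imputation). A channel never observed
#' in training gets mean 0 with a warning.
#'
#' @param batch the training `window_batch` (pre-imputation).
#' @return list with `channel_means` (per modality, numeric per channel).
#' @export
fit_channel_stats <- function(batch) {
  channel_means <- vector("list", length(batch$values))
  names(channel_means) <- names(batch$values)
  for (m in seq_along(batch$values)) {
    v <- batch$values[[m]]
    C <- dim(v)[2L]
    mu <- numeric(C)
    for (c in seq_len(C)) {
      obs <- v[, c, ][is.finite(v[, c, ])]
      if (length(obs) == 0L) {
        warning(sprintf("channel %d of modality '%s' never observed in training; mean set to 0",
                        c, names(batch$values)[m]))
        mu[c] <- 0
      } else mu[c] <- mean(obs)
    }
    channel_means[[m]] <- mu
  }
  list(channel_means = channel_means)
}

#' Z-score a window batch with training-set statistics
#'
#' Standardizes every modality channel as `(x - mean_train) / sd_train`. When
#' `stats` is omitted the batch is treated as the training split and the
#' statistics are fitted from it (pooled over windows and steps, sample sd).
#' Channels with `sd < 1e-8` get divisor 1 and are flagged in
#' `stats$degenerate`.
#'
#' @param batch an imputed `window_batch`.
#' @param stats optional previously fitted statistics (to transform
#'   validation/test splits).
#' @return list with elements `batch` and `stats` (per modality: `mean`,
#'   `sd`, `degenerate` per channel).
#' @export
zscore <- function(batch, stats = NULL) {
  fit <- is.null(stats)
  if (fit) stats <- list()
  for (m in seq_along(batch$values)) {
    v <- batch$values[[m]]
    C <- dim(v)[2L]
    if (fit) {
      mu <- sdv <- numeric(C); degen <- logical(C)
      for (c in seq_len(C)) {
        cells <- as.numeric(v[, c, ])
        mu[c] <- mean(cells)
        s <- stats::sd(cells)
        if (!is.finite(s) || s < 1e-8) { degen[c] <- TRUE; s <- 1 }
        sdv[c] <- s
      }
      stats[[names(batch$values)[m]]] <-
        list(mean = mu, sd = sdv, degenerate = degen,
             channels = batch$channels[[m]])
    } else {
      st <- stats[[names(batch$values)[m]]]
      if (is.null(st)) {
        stop_amfn(sprintf("no fitted statistics for modality '%s'",
                          names(batch$values)[m]))
      }
      if (!identical(st$channels, batch$channels[[m]])) {
        unknown <- setdiff(batch$channels[[m]], st$channels)
        stop_amfn(sprintf("unknown channel(s) in modality '%s': %s",
                          names(batch$values)[m],
                          paste(unknown, collapse = ", ")))
      }
      mu <- st$mean; sdv <- st$sd
    }
    for (c in seq_len(C)) {
      v[, c, ] <- (v[, c, ] - mu[c]) / sdv[c]
    }
    batch$values[[m]] <- v
  }
  list(batch = batch, stats = stats)
}

#' Run the full preprocessing pipeline on a multimodal dataset
#'
#' Executes the fixed stage order align -> segment -> filter -> impute ->
#' z-score, fitting all statistics (channel means for imputation, z-scoring
#' moments) on the training patients only and applying them to every split.
#'
#' @param dataset an `amfn_dataset` (or a list with `records` and `labels`).
#' @param split list with character vectors `train`, `val`, `test` of patient
#'   ids (see [split_dataset()]).
#' @param win,stride window geometry in steps.
#' @param max_missing pooled missing-fraction threshold above which a window
#'   is dropped (strict inequality).
#' @param long_gap longest forward-fillable gap, in steps.
#' @param grid_step,max_gap resampling grid spacing and widest interpolated
#'   neighbour separation (see [align_resample()]).
#' @param align set `FALSE` when records are already on the common integer
#'   grid (the synthetic generator's output), skipping resampling.
#' @return list with `window_batch`es `train`, `val`, `test`, the fitted
#'   `stats`, and a `manifest` (stage order, window counts, drops).
#' @export
preprocess_dataset <- function(dataset, split,
                               win = 256L, stride = 128L,
                               max_missing = 0.4, long_gap = 60L,
                               grid_step = 1, max_gap = 10,
                               align = FALSE) {
  records <- dataset$records
  labels <- dataset$labels
  if (align) {
    # resample every modality of a patient onto the patient's common span,
    # so all modalities share one grid even when their observed spans differ
    records <- lapply(records, function(pr) {
      t0 <- min(vapply(pr, function(r) min(r$timestamps), numeric(1)))
      t1 <- max(vapply(pr, function(r) max(r$timestamps), numeric(1)))
      lapply(pr, align_resample, grid_step = grid_step, max_gap = max_gap,
             t_range = c(t0, t1))
    })
  }
  get_split <- function(ids) {
    b <- build_window_batch(records[ids], labels[labels$patient_id %in% ids, ],
                            win, stride)
    filter_windows(b, max_missing)
  }
  batches <- lapply(split[c("train", "val", "test")], get_split)
  dropped <- vapply(batches, function(b) attr(b, "n_dropped"), numeric(1))

  ch_stats <- fit_channel_stats(batches$train)
  batches <- lapply(batches, impute_batch, stats = ch_stats, long_gap = long_gap)
  ztrain <- zscore(batches$train)
  batches$train <- ztrain$batch
  for (s in c("val", "test")) {
    batches[[s]] <- zscore(batches[[s]], ztrain$stats)$batch
  }
  manifest <- list(
    stage_order = c("align", "segment", "filter", "impute", "zscore"),
    win = win, stride = stride, max_missing = max_missing, long_gap = long_gap,
    n_windows = vapply(batches, n_windows, numeric(1)),
    n_dropped = dropped
  )
  list(train = batches$train, val = batches$val, test = batches$test,
       stats = list(channel = ch_stats, zscore = ztrain$stats),
       manifest = manifest)
}
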