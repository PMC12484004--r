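#' Configuration for the synthetic multimodal generator
#'
#' Builds the configuration object consumed by [generate_dataset()]. The
#' generator emulates the structure of multi-hour ICU recordings: several
#' modalities observed on a common 1-step time grid, each modality a small set
#' of channels driven by its own smooth latent process, with contiguous
#' drop-out gaps so that per-modality coverage is realistically incomplete
#' (defaults give roughly 90% coverage).
#'
#' Each modality `m` owns an independent stationary AR(1) latent trajectory
#' `u_m` (`latent_dim` x `series_length`, autocorrelation 0.9, unit marginal
#' variance) and is observed as `loading_m %*% u_m + noise`. The continuous
#' outcome for a patient is
#' `sum_m coef_m' mean_t(u_m)` over informative modalities plus, for every
#' interaction pair `(a, b)`, `gamma_ab' mean_t(u_a * u_b)`, standardized to
#' zero mean and unit variance across patients, plus Gaussian label noise
#' (so `label_noise_sd` is a relative noise level). For `task = "binary"` the
#' continuous score is thresholded at its median, giving balanced classes by
#' construction. The post-standardization (effective) coefficients are stored
#' in the ground truth.
#'
#' @param n_patients number of patients to simulate.
#' @param n_modalities number of modalities M (>= 2).
#' @param channels_per_modality integer vector of length M; channels per
#'   modality.
#' @param series_length length T of the common time grid, in steps.
#' @param latent_dim dimension of each modality's latent trajectory.
#' @param informative_modalities indices (subset of `1:M`) whose latents enter
#'   the outcome linearly.
#' @param interaction_pairs list of length-2 integer vectors; each pair
#'   `(a, b)` contributes the time-averaged elementwise product of the two
#'   modalities' latents to the outcome, planting a cross-modal interaction.
#' @param noise_sd observation noise standard deviation, scalar or length M.
#' @param missing_rate target missing fraction per modality, scalar or length
#'   M, each in `[0, 1)`.
#' @param gap_length_mean mean length (steps) of contiguous missing gaps.
#' @param task `"regression"` or `"binary"`.
#' @param label_noise_sd standard deviation of the additive label noise.
#' @param seed integer seed; `(config, seed)` fully determines the dataset.
#' @return an object of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_patients = 4, series_length = 64, seed = 1)
#' ds <- generate_dataset(cfg)
#' names(ds)
synth_config <- function(n_patients,
                         n_modalities = 3L,
                         channels_per_modality = rep(2L, n_modalities),
                         series_length = 512L,
                         latent_dim = 4L,
                         informative_modalities = 1L,
                         interaction_pairs = list(),
                         noise_sd = 0.5,
                         missing_rate = 0.1,
                         gap_length_mean = 10,
                         task = c("regression", "binary"),
                         label_noise_sd = 0.1,
                         seed = 1L) {
  task <- match.arg(task)
  M <- as.integer(n_modalities)
  if (M < 2L) stop_amfn("n_modalities must be >= 2")
  if (length(channels_per_modality) != M) {
    stop_amfn("channels_per_modality must have length n_modalities")
  }
  if (length(informative_modalities) < 1L) {
    stop_amfn("informative_modalities must contain at least one modality")
  }
  if (!all(informative_modalities %in% seq_len(M))) {
    stop_amfn("informative_modalities out of range 1..M")
  }
  noise_sd <- rep_len(noise_sd, M)
  missing_rate <- rep_len(missing_rate, M)
  if (any(noise_sd < 0)) stop_amfn("noise_sd must be nonnegative")
  if (any(missing_rate < 0 | missing_rate >= 1)) {
    stop_amfn("missing_rate must lie in [0, 1)")
  }
  if (gap_length_mean <= 0) stop_amfn("gap_length_mean must be positive")
  for (p in interaction_pairs) {
    if (length(p) != 2L || !all(p %in% seq_len(M))) {
      stop_amfn("each interaction pair must be two modality indices in 1..M")
    }
  }
  structure(list(
    n_patients = as.integer(n_patients),
    n_modalities = M,
    channels_per_modality = as.integer(channels_per_modality),
    series_length = as.integer(series_length),
    latent_dim = as.integer(latent_dim),
    informative_modalities = as.integer(informative_modalities),
    interaction_pairs = lapply(interaction_pairs, as.integer),
    noise_sd = noise_sd,
    missing_rate = missing_rate,
    gap_length_mean = gap_length_mean,
    task = task,
    label_noise_sd = label_noise_sd,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# Stationary AR(1) sample path, unit marginal variance, autocorrelation rho.
# The recursion runs through stats::filter (C speed); the first innovation is
# drawn at the stationary scale so the process starts in equilibrium.
ar1_trajectory <- function(ndim, T, rho = 0.9) {
  innov <- matrix(stats::rnorm(ndim * T, sd = sqrt(1 - rho^2)), T, ndim)
  innov[1L, ] <- innov[1L, ] / sqrt(1 - rho^2)
  u <- stats::filter(innov, rho, method = "recursive")
  t(matrix(as.numeric(u), T, ndim))
}

#' Construct a modality record
#'
#' A `modality_record` holds one patient's raw (possibly irregular) time
#' series for one modality: channel names, strictly increasing timestamps and
#' a channels x timestamps value matrix where `NA` marks missing cells.
#'
#' @param patient_id character scalar.
#' @param modality character scalar, the modality name.
#' @param channels character vector of channel names.
#' @param timestamps strictly increasing numeric vector.
#' @param values numeric matrix, `length(channels)` x `length(timestamps)`.
#' @return object of class `modality_record`.
#' @export
modality_record <- function(patient_id, modality, channels, timestamps, values) {
  values <- as.matrix(values)
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    stop_amfn("timestamps must be strictly increasing")
  }
  if (nrow(values) != length(channels) || ncol(values) != length(timestamps)) {
    stop_amfn("values must be a channels x timestamps matrix")
  }
  structure(list(
    patient_id = as.character(patient_id),
    modality = as.character(modality),
    channels = as.character(channels),
    timestamps = as.numeric(timestamps),
    values = values
  ), class = "modality_record")
}

#' Generate a synthetic multimodal dataset with known ground truth
#'
#' Simulates per-patient multimodal time series under the generative model
#' described in [synth_config()], injects contiguous-gap missingness via
#' [inject_missingness()], and returns the complete ground truth (latent
#' trajectories, loading matrices, outcome coefficients, masks) so that
#' recovery can be tested exactly.
#'
#' @param cfg a `synth_config`.
#' @return a list of class `amfn_dataset` with elements
#'   \describe{
#'     \item{records}{list (one per patient) of lists of `modality_record`s,
#'       with `NA` at missing cells.}
#'     \item{labels}{data.frame with columns `patient_id`, `label`.}
#'     \item{ground_truth}{latents, loadings, coefficients, masks, and the
#'       pre-threshold continuous score.}
#'     \item{cfg}{the configuration used.}
#'   }
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    M <- cfg$n_modalities
    T <- cfg$series_length
    ids <- sprintf("P%04d", seq_len(cfg$n_patients))
    modal_names <- sprintf("mod%d", seq_len(M))

    loadings <- lapply(seq_len(M), function(m) {
      matrix(stats::rnorm(cfg$channels_per_modality[m] * cfg$latent_dim,
                          sd = 1 / sqrt(cfg$latent_dim)),
             cfg$channels_per_modality[m], cfg$latent_dim)
    })
    coefs <- lapply(seq_len(M), function(m) {
      if (m %in% cfg$informative_modalities) stats::rnorm(cfg$latent_dim) else
        rep(0, cfg$latent_dim)
    })
    inter_coefs <- lapply(cfg$interaction_pairs, function(p) stats::rnorm(cfg$latent_dim))

    latents <- vector("list", cfg$n_patients)
    records <- vector("list", cfg$n_patients)
    score <- numeric(cfg$n_patients)
    for (p in seq_len(cfg$n_patients)) {
      u <- lapply(seq_len(M), function(m) ar1_trajectory(cfg$latent_dim, T))
      latents[[p]] <- u
      s <- 0
      for (m in cfg$informative_modalities) {
        s <- s + sum(coefs[[m]] * rowMeans(u[[m]]))
      }
      for (k in seq_along(cfg$interaction_pairs)) {
        pr <- cfg$interaction_pairs[[k]]
        s <- s + sum(inter_coefs[[k]] * rowMeans(u[[pr[1L]]] * u[[pr[2L]]]))
      }
      score[p] <- s
      records[[p]] <- lapply(seq_len(M), function(m) {
        C <- cfg$channels_per_modality[m]
        X <- loadings[[m]] %*% u[[m]]
        if (cfg$noise_sd[m] > 0) {
          X <- X + matrix(stats::rnorm(C * T, sd = cfg$noise_sd[m]), C, T)
        }
        modality_record(ids[p], modal_names[m],
                        sprintf("%s_ch%d", modal_names[m], seq_len(C)),
                        seq_len(T) - 1, X)
      })
      names(records[[p]]) <- modal_names
    }
    names(records) <- ids

    # standardize the continuous outcome across patients so label_noise_sd
    # is a relative noise level and downstream losses are commensurate
    mu_s <- mean(score)
    sd_s <- stats::sd(score)
    if (!is.finite(sd_s) || sd_s < 1e-12) sd_s <- 1
    score <- (score - mu_s) / sd_s
    label <- score + stats::rnorm(cfg$n_patients, sd = cfg$label_noise_sd)
    if (cfg$task == "binary") {
      label <- as.integer(label > stats::median(label))
    }

    mseed <- derive_seed(cfg$seed, 1L)
    inj <- inject_missingness(records, cfg$missing_rate, cfg$gap_length_mean, mseed)

    structure(list(
      records = inj$records,
      labels = data.frame(patient_id = ids, label = label,
                          stringsAsFactors = FALSE),
      ground_truth = list(
        latents = latents,
        loadings = loadings,
        coefficients = lapply(coefs, function(cf) cf / sd_s),
        interaction_coefficients = lapply(inter_coefs, function(cf) cf / sd_s),
        score_center = mu_s, score_scale = sd_s,
        intercept = -mu_s / sd_s,
        masks = inj$masks,
        complete_records = records,
        score = score
      ),
      cfg = cfg
    ), class = "amfn_dataset")
  })
}

#' Inject contiguous-gap missingness into modality records
#'
#' Marks cells missing (`NA`) in alternating observed/missing runs. Gap
#' lengths are geometric with mean `gap_length_mean`; observed-run lengths are
#' geometric with mean `gap_length_mean * (1 - rate) / rate`, so the
#' long-run missing fraction converges to `rate` as the series grows. All
#' channels of a modality share the mask, mimicking whole-modality sensor
#' drop-out.
#'
#' @param records list (patients) of lists of `modality_record`s.
#' @param missing_rate per-modality target missing fraction(s) in `[0, 1)`.
#' @param gap_length_mean mean gap length in steps (>= 1 recommended).
#' @param seed integer seed for the gap process.
#' @return list with `records` (values `NA`-ed at missing cells) and `masks`
#'   (per patient per modality, logical channel x time matrices, TRUE =
#'   observed).
#' @export
inject_missingness <- function(records, missing_rate, gap_length_mean, seed) {
  if (gap_length_mean <= 0) stop_amfn("gap_length_mean must be positive")
  M <- length(records[[1L]])
  missing_rate <- rep_len(missing_rate, M)
  if (any(missing_rate < 0 | missing_rate >= 1)) {
    stop_amfn("missing_rate must lie in [0, 1)")
  }
  with_seed(seed, {
    masks <- vector("list", length(records))
    names(masks) <- names(records)
    for (p in seq_along(records)) {
      masks[[p]] <- vector("list", M)
      names(masks[[p]]) <- names(records[[p]])
      for (m in seq_len(M)) {
        rec <- records[[p]][[m]]
        T <- length(rec$timestamps)
        obs <- sample_gap_mask(T, missing_rate[m], gap_length_mean)
        mask <- matrix(rep(obs, each = nrow(rec$values)),
                       nrow(rec$values), T)
        rec$values[!mask] <- NA_real_
        records[[p]][[m]] <- rec
        masks[[p]][[m]] <- mask
      }
    }
    list(records = records, masks = masks)
  })
}

# One observed/missing run-length process over T steps. Returns a logical
# vector, TRUE = observed. rate = 0 short-circuits to all-observed.
sample_gap_mask <- function(T, rate, gap_mean) {
  if (rate == 0) return(rep(TRUE, T))
  obs_mean <- gap_mean * (1 - rate) / rate
  # run length ~ 1 + Geom(p) has mean 1/p
  p_gap <- min(1, 1 / max(gap_mean, 1))
  p_obs <- min(1, 1 / max(obs_mean, 1))
  out <- logical(T)
  pos <- 1L
  observed <- stats::runif(1) >= rate # stationary start state
  while (pos <= T) {
    p <- if (observed) p_obs else p_gap
    len <- 1L + stats::rgeom(1L, p)
    end <- min(T, pos + len - 1L)
    out[pos:end] <- observed
    pos <- end + 1L
    observed <- !observed
  }
  out
}
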