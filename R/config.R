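# Run configuration: a nested list covering every pipeline stage, strict
# parsing (unknown keys rejected with their dotted path), lossless YAML
# round trip, and defaults matching the training protocol above.

#' Default run configuration
#'
#' Returns the fully resolved nested configuration with the package's
#' defaults: 256-step windows with stride 128 and a 40% missingness
#' threshold, embedding dimension 128, four attention heads, two residual
#' GCN layers, a size-128 learnable query, Adam at learning rate 0.001 with
#' cosine annealing, batch size 256, 100 epochs, weight decay 1e-5,
#' gradient clipping at 1.0, dropout 0.5, early-stopping patience 10, and an
#' 80-10-10 patient split.
#'
#' @return nested list of class `amfn_config`.
#' @export
amfn_config <- function() {
  structure(list(
    seed = 1L,
    synthetic = list(
      n_patients = 100L, n_modalities = 3L,
      channels_per_modality = c(2L, 2L, 2L), series_length = 512L,
      latent_dim = 4L, informative_modalities = 1L,
      interaction_pairs = list(), noise_sd = 0.5, missing_rate = 0.1,
      gap_length_mean = 10, task = "regression", label_noise_sd = 0.1
    ),
    preprocess = list(
      window = 256L, stride = 128L, max_missing = 0.4, long_gap = 60L,
      grid_step = 1, max_gap = 10, align = TRUE
    ),
    encoder = list(type = "tcn", dim = 128L, dropout = 0.5),
    fusion = list(
      n_heads = 4L, gcn_layers = 2L, residual = TRUE,
      similarity_clamp = 1e-8, adjacency = "ratio"
    ),
    dcmls = list(
      lambda_rec = 0.1, lambda_align = 0.1, normalize_before_align = TRUE,
      pairs = "co_present", head_input = "concat", stage = "encoder"
    ),
    task = list(loss = "mse", focal_gamma = 2),
    train = list(
      lr = 0.001, epochs = 100L, batch_size = 256L, weight_decay = 1e-5,
      grad_clip = 1.0, patience = 10L, eta_min = 0,
      splits = c(0.8, 0.1, 0.1), cv_folds = 0L # 0 = no cross-validation
    ),
    paths = list(data_dir = "data", out_dir = "runs")
  ), class = "amfn_config")
}

# Strict recursive merge: every user key must exist in the defaults and have
# a compatible type; returns the fully resolved configuration.
merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      stop_amfn(sprintf("unknown configuration key '%s'", here))
    }
    dv <- defaults[[key]]
    uv <- user[[key]]
    if (is.list(dv) && !is.null(names(dv))) {
      if (!is.list(uv)) stop_amfn(sprintf("'%s' must be a mapping", here))
      defaults[[key]] <- merge_config(dv, uv, c(path, key))
    } else {
      if (!is.null(dv) && !is.null(uv)) {
        if (is.numeric(dv) && !is.numeric(uv)) {
          stop_amfn(sprintf("'%s' must be numeric", here))
        }
        if (is.character(dv) && !is.character(uv)) {
          stop_amfn(sprintf("'%s' must be character", here))
        }
        if (is.logical(dv) && !is.logical(uv)) {
          stop_amfn(sprintf("'%s' must be logical", here))
        }
      }
      defaults[[key]] <- uv
    }
  }
  defaults
}

#' Parse a YAML run configuration
#'
#' Reads a YAML file, validates it against the default schema (unknown keys
#' and type mismatches are rejected with the offending dotted path), and
#' returns the fully resolved configuration with defaults applied. An empty
#' file yields all defaults.
#'
#' @param path YAML file path.
#' @return `amfn_config` list.
#' @export
parse_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  # interaction_pairs arrives as a list of 2-vectors; coerce integerish
  cfg <- merge_config(unclass(amfn_config()), user)
  structure(cfg, class = "amfn_config")
}

#' Write a run configuration to YAML
#'
#' The written file parses back to an identical configuration
#' (`parse_config(write_config(cfg, f))` round-trips).
#'
#' @param cfg an `amfn_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_to_synth <- function(cfg) {
  s <- cfg$synthetic
  synth_config(
    n_patients = s$n_patients, n_modalities = s$n_modalities,
    channels_per_modality = s$channels_per_modality,
    series_length = s$series_length, latent_dim = s$latent_dim,
    informative_modalities = s$informative_modalities,
    interaction_pairs = s$interaction_pairs, noise_sd = s$noise_sd,
    missing_rate = s$missing_rate, gap_length_mean = s$gap_length_mean,
    task = s$task, label_noise_sd = s$label_noise_sd, seed = cfg$seed
  )
}

config_to_model_args <- function(cfg, M, channels) {
  list(M = M, channels = channels, win = cfg$preprocess$window,
       d = cfg$encoder$dim, encoder_type = cfg$encoder$type,
       n_heads = cfg$fusion$n_heads, gcn_layers = cfg$fusion$gcn_layers,
       residual = cfg$fusion$residual,
       adjacency = cfg$fusion$adjacency,
       similarity_clamp = cfg$fusion$similarity_clamp,
       dropout = cfg$encoder$dropout,
       task = cfg$synthetic$task,
       task_loss = if (cfg$synthetic$task == "binary" &&
                       cfg$task$loss == "mse") "ce" else cfg$task$loss,
       focal_gamma = cfg$task$focal_gamma,
       head_input = cfg$dcmls$head_input,
       dcmls_stage = cfg$dcmls$stage,
       lambda_rec = cfg$dcmls$lambda_rec,
       lambda_align = cfg$dcmls$lambda_align,
       normalize_before_align = cfg$dcmls$normalize_before_align,
       seed = cfg$seed)
}

config_to_train_args <- function(cfg) {
  t <- cfg$train
  list(lr = t$lr, epochs = t$epochs, batch_size = t$batch_size,
       weight_decay = t$weight_decay, grad_clip = t$grad_clip,
       patience = t$patience, eta_min = t$eta_min, seed = cfg$seed)
}
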