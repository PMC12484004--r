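# Shared fixtures: everything is generated in code at test time.

# A small but structurally complete dataset: 3 modalities, unequal channel
# counts, moderate missingness, short series so preprocessing yields a
# handful of 32-step windows.
tiny_dataset <- function(n_patients = 8, seed = 7, ...) {
  cfg <- synth_config(n_patients = n_patients, n_modalities = 3,
                      channels_per_modality = c(2, 3, 2),
                      series_length = 80, latent_dim = 3,
                      informative_modalities = 1,
                      noise_sd = 0.3, missing_rate = 0.15,
                      gap_length_mean = 5, seed = seed, ...)
  generate_dataset(cfg)
}

tiny_prep <- function(ds = tiny_dataset(), split_seed = 3) {
  split <- split_dataset(ds$labels$patient_id, seed = split_seed)
  preprocess_dataset(ds, split, win = 32L, stride = 16L, long_gap = 5L)
}

tiny_model <- function(d = 6L, seed = 5, ...) {
  init_model(M = 3, channels = c(2, 3, 2), win = 32L, d = d,
             dropout = 0, seed = seed, ...)
}

# Uniform-grid modality record with optional NA cells.
grid_record <- function(values, patient = "P1", modality = "mod1") {
  values <- as.matrix(values)
  modality_record(patient, modality,
                  sprintf("ch%d", seq_len(nrow(values))),
                  seq_len(ncol(values)) - 1, values)
}
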