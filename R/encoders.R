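# Modality-specific encoders map a (channels x window) matrix to a d-vector.
# Three architectures are available:
#   tcn  - two temporal convolutions (kernel 5, stride 2, ReLU) -> global
#          average pool -> linear projection to d (default),
#   gru  - gated recurrent unit over the window, last hidden state -> linear,
#   mean - per-channel time average -> linear (the "no feature extraction"
#          ablation encoder).
# All modalities project into the same d-dimensional space.

#' Encode one modality window into a d-dimensional embedding
#'
#' Deterministic in eval mode (`train = FALSE`, the default: dropout is
#' disabled). An absent modality returns the zero vector, which downstream
#' softmax normalizations exclude via the presence flag.
#'
#' @param window numeric channels x window-length matrix, fully imputed.
#' @param modality modality index.
#' @param model an `amfn_model` from [init_model()].
#' @param present logical; `FALSE` returns the zero embedding.
#' @param train logical; enables dropout when TRUE.
#' @return numeric vector of length `model$cfg$d`.
#' @export
encode <- function(window, modality, model, present = TRUE, train = FALSE) {
  d <- model$cfg$d
  if (!present) return(numeric(d))
  enc <- model$params$encoders[[modality]]
  C <- enc$n_channels
  if (nrow(window) != C) {
    stop_amfn(sprintf("modality %d expects %d channels, got %d",
                      modality, C, nrow(window)))
  }
  X <- matrix(as.numeric(window), 1L, C * ncol(window)) # channel-fastest layout
  encoder_forward(X, enc, model$cfg$encoder_type, C, train = train,
                  dropout = model$cfg$dropout)$h[1L, ]
}

#' Standardize embeddings with training-set statistics
#'
#' Applies the per-dimension affine standardization
#' `h_norm = (h - mu) / sigma` to each modality's embeddings, where `mu` and
#' `sigma` are fitted over the training set (frozen statistics, not batch
#' statistics). Dimensions with `sigma < 1e-8` get divisor 1 and are flagged.
#'
#' @param h_set list (one entry per modality) of samples x d embedding
#'   matrices.
#' @param stats optional fitted statistics; omitted means `h_set` is the
#'   training set and statistics are fitted from it.
#' @return list with `h_norm` (same shape as `h_set`) and `stats` (per
#'   modality: `mean`, `sd`, `degenerate` d-vectors).
#' @export
normalize_embeddings <- function(h_set, stats = NULL) {
  if (is.null(stats)) {
    stats <- lapply(h_set, function(H) {
      mu <- colMeans(H)
      sdv <- apply(H, 2L, stats::sd)
      degen <- !is.finite(sdv) | sdv < 1e-8
      sdv[degen] <- 1
      list(mean = mu, sd = sdv, degenerate = degen)
    })
  }
  h_norm <- mapply(function(H, st) {
    sweep(sweep(H, 2L, st$mean, "-"), 2L, st$sd, "/")
  }, h_set, stats, SIMPLIFY = FALSE)
  list(h_norm = h_norm, stats = stats)
}
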