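# Dynamic cross-modal learning strategy: sigmoid modality gating, the
# contrastive alignment penalty between co-present modality pairs,
# context-aware query fusion, and the composite training objective.

#' Adaptive per-modality gating
#'
#' Computes the scalar importance weight `gamma_m = sigmoid(w_m' h_m)` for
#' every modality and rescales the embeddings, `h_gated_m = gamma_m * h_m`.
#' The gate is a soft selector: uninformative modalities can be suppressed
#' without being removed. Absent modalities are gated to 0.
#'
#' @param h M x d matrix of modality embeddings.
#' @param params list with `w`: M x d matrix (row m is the gate vector of
#'   modality m) or a list of d-vectors.
#' @param present length-M 0/1 vector, default all present.
#' @return list with `gamma` (length M, in (0,1) for present modalities, 0
#'   for absent ones) and `h_gated` (M x d).
#' @export
adaptive_gate <- function(h, params, present = rep(1, nrow(h))) {
  W <- params$w
  if (is.list(W)) W <- do.call(rbind, W)
  stopifnot(all(dim(W) == dim(h)))
  gamma <- sigmoid(rowSums(W * h))
  gamma <- gamma * as.numeric(present)
  list(gamma = gamma, h_gated = h * gamma)
}

#' Contrastive alignment loss over positive modality pairs
#'
#' Sums squared Euclidean distances `||h_i - h_j||^2` over the positive pair
#' set. With `normalize = TRUE` (default) embeddings are L2-normalized to
#' unit length first, so each pair's term identically equals
#' `2 - 2 cos(h_i, h_j)` and the loss is a pure cosine-proximity penalty.
#'
#' @param h M x d matrix of modality embeddings.
#' @param pairs list of length-2 index vectors, the positive pair set P. By
#'   default all unordered pairs of rows.
#' @param normalize L2-normalize rows before the loss (default TRUE).
#' @return nonnegative scalar; 0 iff all paired embeddings coincide. An
#'   empty pair set returns 0 with a warning.
#' @export
alignment_loss <- function(h, pairs = NULL, normalize = TRUE) {
  M <- nrow(h)
  if (is.null(pairs)) {
    pairs <- list()
    if (M >= 2L) {
      for (i in seq_len(M - 1L)) for (j in (i + 1L):M) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(pairs) == 0L) {
    warning("alignment_loss: empty pair set, returning 0")
    return(0)
  }
  if (normalize) {
    nrm <- pmax(sqrt(rowSums(h^2)), 1e-12)
    h <- h / nrm
  }
  s <- 0
  for (p in pairs) {
    s <- s + sum((h[p[1L], ] - h[p[2L], ])^2)
  }
  s
}

#' Context-aware fusion with a learned query vector
#'
#' Computes fusion weights `beta_m = softmax_m(q' h_gated_m)` over present
#' modalities and the fused representation `F = sum_m beta_m h_gated_m`,
#' which therefore lies in the convex hull of the gated embeddings.
#'
#' @param h_gated M x d matrix of gated modality embeddings.
#' @param present length-M 0/1 vector.
#' @param query length-d numeric, the learned query vector.
#' @return list with `beta` (length M, sums to 1 over present modalities)
#'   and `f` (length d).
#' @export
context_fusion <- function(h_gated, present, query) {
  present <- as.numeric(present)
  if (sum(present) < 1) stop_amfn("context_fusion: all modalities absent")
  logits <- as.numeric(h_gated %*% query)
  beta <- drop(masked_softmax(matrix(logits, 1L), matrix(present > 0, 1L)))
  list(beta = beta, f = as.numeric(t(h_gated) %*% beta))
}

#' Composite training objective
#'
#' `L = L_task + lambda_rec * L_rec + lambda_align * L_align`, combining the
#' task loss (MSE for regression; cross-entropy or focal loss for
#' classification), the masked reconstruction loss of the per-modality
#' decoders, and the contrastive alignment penalty.
#'
#' @param task_loss,rec_loss,align_loss finite numeric scalars.
#' @param weights list with nonnegative `lambda_rec`, `lambda_align`.
#' @return scalar total loss.
#' @export
total_objective <- function(task_loss, rec_loss, align_loss, weights) {
  lr <- weights$lambda_rec %||% 0
  la <- weights$lambda_align %||% 0
  if (lr < 0 || la < 0) stop_amfn("loss weights must be nonnegative")
  if (!all(is.finite(c(task_loss, rec_loss, align_loss)))) {
    stop_amfn("loss components must be finite")
  }
  task_loss + lr * rec_loss + la * align_loss
}

#' Focal loss for binary classification
#'
#' `FL = -mean((1 - p_t)^gamma * log(p_t))` with `p_t` the probability
#' assigned to the true class. `gamma = 0` recovers binary cross-entropy;
#' larger `gamma` down-weights well-classified samples, which helps under
#' class imbalance (e.g. mortality prediction).
#'
#' @param p predicted probabilities of class 1.
#' @param y 0/1 labels.
#' @param gamma focusing parameter, nonnegative (default 2).
#' @return scalar loss.
#' @export
focal_loss <- function(p, y, gamma = 2) {
  stopifnot(gamma >= 0)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  pt <- ifelse(y == 1, p, 1 - p)
  mean(-(1 - pt)^gamma * log(pt))
}
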