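# The fusion core operating on one sample's M x d stack of modality
# embeddings: bilinear cross-modal attention, a similarity-based modality
# graph, GCN refinement with residuals, and the concatenated graph-level
# representation. These are the reference (single-sample) implementations;
# the trainer uses batched equivalents that are tested against these.

#' Bilinear cross-modal attention
#'
#' Computes attention weights `alpha[i, j] = softmax_j(h_i' W_a h_j)` over
#' present modalities (absent columns are masked out before the softmax; the
#' self term is included) and the attended embeddings
#' `h_att[i, ] = sum_j alpha[i, j] h[j, ]`. With `n_heads > 1` each head owns
#' its own bilinear matrix; head outputs are concatenated and linearly
#' projected back to d. With a single head no projection is applied, so the
#' operation is exactly the plain bilinear-softmax.
#'
#' @param h_norm M x d matrix of standardized modality embeddings.
#' @param present length-M 0/1 vector of modality presence.
#' @param params list with `Wa` (list of d x d matrices, one per head) and,
#'   for multi-head, `proj` (`n_heads * d` x d projection).
#' @return list with `alpha` (M x M, averaged over heads; each present row a
#'   probability vector, absent rows zero) and `h_att` (M x d, absent rows
#'   zero).
#' @export
cross_modal_attention <- function(h_norm, present, params) {
  M <- nrow(h_norm)
  present <- as.numeric(present)
  if (sum(present) < 1) stop_amfn("cross_modal_attention: all modalities absent")
  heads <- params$Wa
  K <- length(heads)
  mask <- matrix(present > 0, M, M, byrow = TRUE)
  alpha_heads <- vector("list", K)
  h_cat <- matrix(0, M, 0)
  for (k in seq_len(K)) {
    S <- (h_norm %*% heads[[k]]) %*% t(h_norm)
    a <- masked_softmax(S, mask)
    a[present == 0, ] <- 0
    alpha_heads[[k]] <- a
    h_cat <- cbind(h_cat, a %*% h_norm)
  }
  h_att <- if (K > 1L) h_cat %*% params$proj else h_cat
  h_att[present == 0, ] <- 0
  alpha <- Reduce(`+`, alpha_heads) / K
  list(alpha = alpha, h_att = h_att)
}

#' Similarity-based modality graph
#'
#' Builds the row-stochastic adjacency matrix of the per-sample modality
#' graph. Edge weights start from cosine similarity between embeddings; each
#' row is then normalized by its sum over present modalities. Because the
#' ratio normalization is ill-defined for mixed-sign similarities,
#' similarities are clamped below at `clamp` first (default mode); a masked
#' softmax over raw similarities is available as an alternative.
#'
#' @param h M x d matrix of modality embeddings.
#' @param present length-M 0/1 vector.
#' @param clamp lower clamp applied to similarities before ratio
#'   normalization (default 1e-8).
#' @param mode `"ratio"` (clamped similarity / row sum) or `"softmax"`.
#' @return M x M adjacency with nonnegative entries; each present row sums
#'   to 1, absent rows/columns are zero.
#' @export
build_modality_graph <- function(h, present, clamp = 1e-8,
                                 mode = c("ratio", "softmax")) {
  mode <- match.arg(mode)
  M <- nrow(h)
  present <- as.numeric(present)
  if (sum(present) < 1) stop_amfn("build_modality_graph: all modalities absent")
  nrm <- sqrt(rowSums(h^2))
  if (any(nrm < 1e-12 & present > 0)) {
    warning("zero-norm embedding: its similarities are set to the clamp value")
  }
  S <- matrix(clamp, M, M)
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (nrm[i] >= 1e-12 && nrm[j] >= 1e-12) {
        S[i, j] <- sum(h[i, ] * h[j, ]) / (nrm[i] * nrm[j])
      }
    }
  }
  mask <- matrix(present > 0, M, M, byrow = TRUE)
  if (mode == "ratio") {
    S[S < clamp] <- clamp
    S[!mask] <- 0
    A <- S / ifelse(rowSums(S) > 0, rowSums(S), 1)
  } else {
    A <- masked_softmax(S, mask)
  }
  A[present == 0, ] <- 0
  A
}

#' GCN propagation over the modality graph
#'
#' Refines the attended embeddings along the modality graph:
#' `H^(l+1) = act(A H^(l) W^(l)) [+ H^(l)]`, starting from `H^(0) = h_att`.
#' Residual connections are on by default (two layers);
#' `residual = FALSE` restores the bare propagation rule, and
#' `activation = "identity"` supports oracle testing.
#'
#' @param h_att M x d matrix, `H^(0)`.
#' @param A M x M row-stochastic adjacency.
#' @param params list with `W` (list of d x d layer matrices), and optional
#'   `residual` (default TRUE) and `activation` (`"relu"` or `"identity"`).
#' @return M x d matrix `H^(L)`.
#' @export
gcn_propagate <- function(h_att, A, params) {
  if (ncol(A) != nrow(h_att)) stop_amfn("gcn_propagate: A and H dimensions differ")
  act <- switch(params$activation %||% "relu",
                relu = relu, identity = identity,
                stop_amfn("unknown activation"))
  residual <- params$residual %||% TRUE
  H <- h_att
  for (W in params$W) {
    if (nrow(W) != ncol(H)) stop_amfn("gcn_propagate: weight dimension mismatch")
    out <- act(A %*% H %*% W)
    H <- if (residual) out + H else out
  }
  H
}

#' Concatenate refined modality embeddings into the graph-level vector
#'
#' Stacks the M rows of `H^(L)` in fixed modality order into one vector of
#' length `M * d`. Absent modalities contribute their (zero-input) refined
#' rows, preserving the block layout.
#'
#' @param H M x d matrix.
#' @param present length-M 0/1 vector (unused for layout, kept for the module
#'   contract).
#' @return numeric vector of length `M * d`; block m is row m of `H`.
#' @export
concat_graph_embedding <- function(H, present = rep(1, nrow(H))) {
  as.numeric(t(H))
}
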