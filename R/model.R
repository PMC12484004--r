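# Full model assembly. The forward pass composes, per batch:
#   modality encoders -> embedding standardization (frozen training stats)
#   -> bilinear cross-modal attention -> similarity graph -> GCN with
#   residuals -> concatenated graph embedding Z
#   -> sigmoid gating -> context-aware query fusion F
#   -> linear prediction head on concat(Z, F),
# with the composite objective task + lambda_rec * reconstruction +
# lambda_align * alignment. The backward pass is hand-derived and batched;
# the adjacency matrix is treated as a constant during differentiation
# (gradients do not flow through the cosine-similarity graph weights).

#' Initialize an adaptive multimodal fusion model
#'
#' Creates the parameter set for the full network. Fully connected weights
#' use Xavier initialization, convolutional weights Kaiming initialization.
#'
#' @param M number of modalities.
#' @param channels integer vector of length M, channels per modality.
#' @param win window length in steps (default 256).
#' @param d shared embedding dimension (default 128).
#' @param encoder_type `"tcn"` (two temporal convolutions, kernel 5, stride
#'   2), `"gru"`, or `"mean"` (channel average + linear; the
#'   no-feature-extraction ablation encoder).
#' @param n_heads number of bilinear attention heads (default 4); 1
#'   recovers the plain single-head bilinear attention.
#' @param gcn_layers number of graph-convolution layers (default 2).
#' @param residual use residual connections in the GCN (default TRUE).
#' @param adjacency `"ratio"` or `"softmax"` similarity normalization.
#' @param similarity_clamp lower clamp for similarities before ratio
#'   normalization.
#' @param dropout encoder dropout probability (default 0.5).
#' @param task `"regression"` or `"binary"`.
#' @param task_loss `"mse"`, `"ce"`, or `"focal"`.
#' @param focal_gamma focusing parameter of the focal loss.
#' @param head_input `"concat"` (default), `"Z"`, or `"F"`: which fused
#'   representation feeds the prediction head.
#' @param dcmls_stage `"encoder"` (default) runs gating and context fusion
#'   on the standardized encoder embeddings as a branch parallel to the
#'   graph pipeline; `"gcn"` applies them to the GCN-refined embeddings.
#' @param lambda_rec,lambda_align weights of the reconstruction and
#'   alignment losses.
#' @param normalize_before_align L2-normalize embeddings before the
#'   alignment loss (default TRUE).
#' @param ablate character vector; any of `"attention"` (identity in place
#'   of cross-modal attention), `"gating"` (all gates fixed at 1).
#' @param seed integer seed for the initialization RNG.
#' @return object of class `amfn_model` with elements `cfg`, `params`,
#'   `emb_stats`.
#' @export
init_model <- function(M, channels, win = 256L, d = 128L,
                       encoder_type = c("tcn", "gru", "mean"),
                       n_heads = 4L, gcn_layers = 2L, residual = TRUE,
                       adjacency = c("ratio", "softmax"),
                       similarity_clamp = 1e-8,
                       dropout = 0.5,
                       task = c("regression", "binary"),
                       task_loss = NULL, focal_gamma = 2,
                       head_input = c("concat", "Z", "F"),
                       dcmls_stage = c("encoder", "gcn"),
                       lambda_rec = 0.1, lambda_align = 0.1,
                       normalize_before_align = TRUE,
                       ablate = character(0),
                       seed = 1L) {
  encoder_type <- match.arg(encoder_type)
  adjacency <- match.arg(adjacency)
  task <- match.arg(task)
  head_input <- match.arg(head_input)
  dcmls_stage <- match.arg(dcmls_stage)
  if (is.null(task_loss)) task_loss <- if (task == "regression") "mse" else "ce"
  stopifnot(task_loss %in% c("mse", "ce", "focal"))
  stopifnot(length(channels) == M)
  bad <- setdiff(ablate, c("attention", "gating"))
  if (length(bad)) stop_amfn(sprintf("unknown ablation '%s'", bad[1L]))

  cfg <- list(M = M, channels = as.integer(channels), win = as.integer(win),
              d = as.integer(d), encoder_type = encoder_type,
              n_heads = as.integer(n_heads), gcn_layers = as.integer(gcn_layers),
              residual = residual, adjacency = adjacency,
              similarity_clamp = similarity_clamp, dropout = dropout,
              task = task, task_loss = task_loss, focal_gamma = focal_gamma,
              head_input = head_input, dcmls_stage = dcmls_stage,
              lambda_rec = lambda_rec,
              lambda_align = lambda_align,
              normalize_before_align = normalize_before_align,
              ablate = ablate)

  params <- with_seed(seed, {
    p <- list()
    p$encoders <- lapply(seq_len(M), function(m) {
      init_encoder(encoder_type, channels[m], win, d)
    })
    p$decoders <- lapply(seq_len(M), function(m) {
      list(Wd = xavier_init(d, channels[m] * win),
           bd = numeric(channels[m] * win))
    })
    if (!"attention" %in% ablate) {
      p$Wa <- lapply(seq_len(n_heads), function(k) xavier_init(d, d))
      if (n_heads > 1L) p$proj <- xavier_init(n_heads * d, d)
    }
    p$gcn <- lapply(seq_len(gcn_layers), function(l) xavier_init(d, d))
    if (!"gating" %in% ablate) {
      p$gate <- matrix(stats::rnorm(M * d, sd = 1 / sqrt(d)), M, d)
    }
    p$query <- stats::rnorm(d, sd = 1 / sqrt(d))
    head_dim <- switch(head_input, concat = (M + 1L) * d, Z = M * d, F = d)
    p$head_W <- xavier_init(head_dim, 1L)
    p$head_b <- 0
    p
  })
  emb_stats <- lapply(seq_len(M), function(m) list(mean = numeric(d),
                                                   sd = rep(1, d)))
  structure(list(cfg = cfg, params = params, emb_stats = emb_stats),
            class = "amfn_model")
}

# Convert a window_batch into the flat matrices the model consumes:
# per-modality n x (C * win) value/mask matrices in channel-fastest layout.
batch_to_views <- function(batch) {
  flat <- function(a) {
    n <- dim(a)[1L]; C <- dim(a)[2L]; W <- dim(a)[3L]
    matrix(aperm(a, c(1L, 2L, 3L)), n, C * W) # (c fastest, t slower)
  }
  list(X = lapply(batch$values, flat),
       mask = lapply(batch$masks, function(m) flat(m * 1)),
       present = unname(batch$modality_present * 1),
       y = unname(batch$labels))
}

encode_all <- function(model, X, present, train = FALSE) {
  cfg <- model$cfg
  h <- caches <- vector("list", cfg$M)
  for (m in seq_len(cfg$M)) {
    fw <- encoder_forward(X[[m]], model$params$encoders[[m]],
                          cfg$encoder_type, cfg$channels[m],
                          train = train, dropout = cfg$dropout)
    h[[m]] <- fw$h * present[, m] # absent modality contributes a zero vector
    caches[[m]] <- fw$cache
  }
  list(h = h, caches = caches)
}

#' Refit embedding-standardization statistics
#'
#' Recomputes the per-dimension mean/sd of each modality's training
#' embeddings (present samples only) and freezes them in the model. The
#' trainer calls this once before the first epoch; the statistics are
#' constants during backpropagation and for the rest of the run.
#'
#' @param model an `amfn_model`.
#' @param views output of `batch_to_views()` on the training batch.
#' @return the model with updated `emb_stats`.
#' @keywords internal
refit_emb_stats <- function(model, views) {
  enc <- encode_all(model, views$X, views$present, train = FALSE)
  for (m in seq_len(model$cfg$M)) {
    rows <- views$present[, m] > 0
    H <- enc$h[[m]][rows, , drop = FALSE]
    if (nrow(H) >= 2L) {
      mu <- colMeans(H)
      sdv <- apply(H, 2L, stats::sd)
      sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
      model$emb_stats[[m]] <- list(mean = mu, sd = sdv)
    }
  }
  model
}

# Batched masked softmax across list-of-column logits: logits n x M.
# Returns n x M weights, rows renormalized over present entries.
batch_masked_softmax <- function(logits, present) {
  masked_softmax(logits, present > 0)
}

# ---- forward ---------------------------------------------------------------

model_forward <- function(model, views, train = FALSE, compute_loss = TRUE) {
  cfg <- model$cfg
  M <- cfg$M; d <- cfg$d
  present <- views$present
  n <- nrow(present)
  if (any(rowSums(present) < 1)) stop_amfn("sample with all modalities absent")

  enc <- encode_all(model, views$X, present, train = train)
  Hn <- vector("list", M)
  for (m in seq_len(M)) {
    st <- model$emb_stats[[m]]
    Hn[[m]] <- sweep(sweep(enc$h[[m]], 2L, st$mean, "-"), 2L, st$sd, "/") *
      present[, m]
  }

  # cross-modal attention (multi-head bilinear)
  attn <- NULL
  if (!"attention" %in% cfg$ablate) {
    K <- cfg$n_heads
    attn <- list(HW = vector("list", K), alpha = vector("list", K),
                 hcat = vector("list", M))
    hhat <- vector("list", M)
    for (i in seq_len(M)) attn$hcat[[i]] <- matrix(0, n, 0)
    for (k in seq_len(K)) {
      Wa <- model$params$Wa[[k]]
      HWk <- lapply(Hn, function(H) H %*% Wa)
      Sk <- vector("list", M)
      Ak <- vector("list", M)
      for (i in seq_len(M)) {
        S <- matrix(0, n, M)
        for (j in seq_len(M)) S[, j] <- rowSums(HWk[[i]] * Hn[[j]])
        a <- batch_masked_softmax(S, present) * present[, i]
        Sk[[i]] <- S; Ak[[i]] <- a
        hh <- matrix(0, n, d)
        for (j in seq_len(M)) hh <- hh + a[, j] * Hn[[j]]
        attn$hcat[[i]] <- cbind(attn$hcat[[i]], hh)
      }
      attn$HW[[k]] <- HWk
      attn$alpha[[k]] <- Ak
    }
    for (i in seq_len(M)) {
      hhat[[i]] <- if (K > 1L) attn$hcat[[i]] %*% model$params$proj else
        attn$hcat[[i]]
    }
  } else {
    hhat <- Hn
  }

  # similarity graph (constant w.r.t. gradients)
  A <- build_graph_batch(Hn, present, cfg$similarity_clamp, cfg$adjacency)

  # GCN with residuals
  gcn_cache <- list()
  H <- hhat
  for (l in seq_len(cfg$gcn_layers)) {
    Wl <- model$params$gcn[[l]]
    HW <- lapply(H, function(x) x %*% Wl)
    pre <- vector("list", M)
    Hnew <- vector("list", M)
    for (i in seq_len(M)) {
      g <- matrix(0, n, d)
      for (j in seq_len(M)) g <- g + A[[i]][, j] * HW[[j]]
      pre[[i]] <- g
      Hnew[[i]] <- if (cfg$residual) pmax(g, 0) + H[[i]] else pmax(g, 0)
    }
    gcn_cache[[l]] <- list(H_in = H, pre = pre)
    H <- Hnew
  }
  Z <- do.call(cbind, H)

  # gating and fusion read either the GCN-refined embeddings (default:
  # DCMLS is the final stage of the pipeline) or the standardized encoder
  # embeddings (parallel-branch wiring)
  Hsrc <- if (cfg$dcmls_stage == "gcn") H else Hn
  if (!"gating" %in% cfg$ablate) {
    gate_logit <- matrix(0, n, M)
    for (m in seq_len(M)) gate_logit[, m] <- Hsrc[[m]] %*% model$params$gate[m, ]
    gamma <- sigmoid(gate_logit) * present
  } else {
    gate_logit <- NULL
    gamma <- present
  }
  G <- vector("list", M)
  for (m in seq_len(M)) G[[m]] <- gamma[, m] * Hsrc[[m]]

  # context-aware fusion
  flog <- matrix(0, n, M)
  for (m in seq_len(M)) flog[, m] <- G[[m]] %*% model$params$query
  beta <- batch_masked_softmax(flog, present)
  Fv <- matrix(0, n, d)
  for (m in seq_len(M)) Fv <- Fv + beta[, m] * G[[m]]

  U <- switch(cfg$head_input, concat = cbind(Z, Fv), Z = Z, F = Fv)
  yhat <- unname(drop(U %*% model$params$head_W)) + model$params$head_b

  out <- list(yhat = yhat, gamma = gamma, beta = beta, Z = Z, Fv = Fv,
              Hn = Hn, h = enc$h,
              cache = list(enc = enc, attn = attn, hhat = hhat, A = A,
                           gcn = gcn_cache, HL = H, Hsrc = Hsrc, G = G,
                           gate_logit = gate_logit, U = U))
  if (cfg$task == "binary") out$prob <- sigmoid(yhat)

  if (compute_loss && !is.null(views$y)) {
    out$loss <- model_losses(model, views, out)
  }
  out
}

build_graph_batch <- function(Hn, present, clamp, mode) {
  M <- length(Hn)
  n <- nrow(Hn[[1L]])
  nrm <- lapply(Hn, function(H) pmax(sqrt(rowSums(H^2)), 1e-12))
  A <- vector("list", M)
  for (i in seq_len(M)) {
    S <- matrix(0, n, M)
    for (j in seq_len(M)) {
      S[, j] <- rowSums(Hn[[i]] * Hn[[j]]) / (nrm[[i]] * nrm[[j]])
    }
    if (mode == "ratio") {
      S <- pmax(S, clamp)
      S <- S * present
      A[[i]] <- (S / pmax(rowSums(S), 1e-300)) * present[, i]
    } else {
      A[[i]] <- batch_masked_softmax(S, present) * present[, i]
    }
  }
  A
}

model_losses <- function(model, views, fw) {
  cfg <- model$cfg
  n <- length(fw$yhat)
  y <- views$y
  if (cfg$task == "regression") {
    task <- mean((fw$yhat - y)^2)
  } else {
    p <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
    if (cfg$task_loss == "focal") {
      task <- focal_loss(p, y, cfg$focal_gamma)
    } else {
      task <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
    }
  }
  rec <- 0
  if (cfg$lambda_rec > 0) {
    for (m in seq_len(cfg$M)) {
      dec <- model$params$decoders[[m]]
      rec <- rec + cpp_rec_loss(fw$Hn[[m]], dec$Wd, dec$bd, views$X[[m]],
                                views$mask[[m]], 1, FALSE)$loss
    }
    rec <- rec / cfg$M
  }
  align <- 0
  if (cfg$lambda_align > 0 && cfg$M >= 2L) {
    Hu <- align_inputs(fw$Hn, cfg$normalize_before_align)
    for (i in seq_len(cfg$M - 1L)) for (j in (i + 1L):cfg$M) {
      w <- views$present[, i] * views$present[, j]
      align <- align + sum(w * rowSums((Hu$u[[i]] - Hu$u[[j]])^2)) / n
    }
  }
  total <- task + cfg$lambda_rec * rec + cfg$lambda_align * align
  list(task = task, rec = rec, align = align, total = total)
}

align_inputs <- function(Hn, normalize) {
  if (!normalize) return(list(u = Hn, nrm = NULL))
  nrm <- lapply(Hn, function(H) pmax(sqrt(rowSums(H^2)), 1e-12))
  u <- mapply(function(H, s) H / s, Hn, nrm, SIMPLIFY = FALSE)
  list(u = u, nrm = nrm)
}

# ---- backward --------------------------------------------------------------

model_backward <- function(model, views, fw) {
  cfg <- model$cfg
  M <- cfg$M; d <- cfg$d
  n <- length(fw$yhat)
  present <- views$present
  y <- views$y
  g <- list()

  # task loss -> dyhat
  if (cfg$task == "regression") {
    dyhat <- 2 * (fw$yhat - y) / n
  } else {
    p <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
    if (cfg$task_loss == "focal") {
      gm <- cfg$focal_gamma
      pt <- ifelse(y == 1, p, 1 - p)
      dLdq <- -(1 - pt)^gm / pt
      if (gm > 0) dLdq <- dLdq + gm * (1 - pt)^(gm - 1) * log(pt)
      dyhat <- dLdq * (2 * y - 1) * p * (1 - p) / n
    } else {
      dyhat <- (p - y) / n
    }
  }

  # head
  dyhat_m <- matrix(dyhat, n, 1L)
  g$head_W <- crossprod(fw$cache$U, dyhat_m)
  g$head_b <- sum(dyhat)
  dU <- dyhat_m %*% t(model$params$head_W)
  if (cfg$head_input == "concat") {
    dZ <- dU[, seq_len(M * d), drop = FALSE]
    dF <- dU[, M * d + seq_len(d), drop = FALSE]
  } else if (cfg$head_input == "Z") {
    dZ <- dU; dF <- matrix(0, n, d)
  } else {
    dZ <- matrix(0, n, M * d); dF <- dU
  }

  dHn <- lapply(seq_len(M), function(m) matrix(0, n, d))
  dHsrc <- lapply(seq_len(M), function(m) matrix(0, n, d))

  # context fusion backward
  beta <- fw$beta
  G <- fw$cache$G
  Hsrc <- fw$cache$Hsrc
  dG <- vector("list", M)
  dbeta <- matrix(0, n, M)
  for (m in seq_len(M)) {
    dG[[m]] <- beta[, m] * dF
    dbeta[, m] <- rowSums(dF * G[[m]])
  }
  dot <- rowSums(beta * dbeta)
  dflog <- beta * (dbeta - dot)
  g$query <- numeric(d)
  for (m in seq_len(M)) {
    g$query <- g$query + drop(crossprod(G[[m]], dflog[, m]))
    dG[[m]] <- dG[[m]] + outer(dflog[, m], model$params$query)
  }

  # gating backward
  if (!"gating" %in% cfg$ablate) {
    s <- sigmoid(fw$cache$gate_logit)
    g$gate <- matrix(0, M, d)
    for (m in seq_len(M)) {
      dgam <- rowSums(dG[[m]] * Hsrc[[m]])
      dHsrc[[m]] <- dHsrc[[m]] + fw$gamma[, m] * dG[[m]]
      dlogit <- dgam * present[, m] * s[, m] * (1 - s[, m])
      g$gate[m, ] <- drop(crossprod(Hsrc[[m]], dlogit))
      dHsrc[[m]] <- dHsrc[[m]] + outer(dlogit, model$params$gate[m, ])
    }
  } else {
    for (m in seq_len(M)) dHsrc[[m]] <- dHsrc[[m]] + present[, m] * dG[[m]]
  }

  # Z / GCN backward (adjacency treated as constant); the DCMLS gradient
  # joins before the GCN when gating reads the refined embeddings
  dHL <- lapply(seq_len(M), function(m) dZ[, (m - 1L) * d + seq_len(d),
                                           drop = FALSE])
  if (cfg$dcmls_stage == "gcn") {
    for (m in seq_len(M)) dHL[[m]] <- dHL[[m]] + dHsrc[[m]]
  } else {
    for (m in seq_len(M)) dHn[[m]] <- dHn[[m]] + dHsrc[[m]]
  }
  g$gcn <- vector("list", cfg$gcn_layers)
  A <- fw$cache$A
  for (l in rev(seq_len(cfg$gcn_layers))) {
    cc <- fw$cache$gcn[[l]]
    Wl <- model$params$gcn[[l]]
    dpre <- vector("list", M)
    for (i in seq_len(M)) dpre[[i]] <- dHL[[i]] * (cc$pre[[i]] > 0)
    dHin <- if (cfg$residual) dHL else lapply(seq_len(M), function(m)
      matrix(0, n, d))
    dWl <- matrix(0, d, d)
    for (j in seq_len(M)) {
      dHWj <- matrix(0, n, d)
      for (i in seq_len(M)) dHWj <- dHWj + A[[i]][, j] * dpre[[i]]
      dWl <- dWl + crossprod(cc$H_in[[j]], dHWj)
      dHin[[j]] <- dHin[[j]] + dHWj %*% t(Wl)
    }
    g$gcn[[l]] <- dWl
    dHL <- dHin
  }
  dhhat <- dHL

  # attention backward
  if (!"attention" %in% cfg$ablate) {
    K <- cfg$n_heads
    attn <- fw$cache$attn
    g$Wa <- lapply(seq_len(K), function(k) matrix(0, d, d))
    if (K > 1L) {
      g$proj <- matrix(0, K * d, d)
      dhcat <- vector("list", M)
      for (i in seq_len(M)) {
        g$proj <- g$proj + crossprod(attn$hcat[[i]], dhhat[[i]])
        dhcat[[i]] <- dhhat[[i]] %*% t(model$params$proj)
      }
    } else {
      dhcat <- dhhat
    }
    for (k in seq_len(K)) {
      Wa <- model$params$Wa[[k]]
      HWk <- attn$HW[[k]]
      Ak <- attn$alpha[[k]]
      for (i in seq_len(M)) {
        dhh <- dhcat[[i]][, (k - 1L) * d + seq_len(d), drop = FALSE]
        a <- Ak[[i]]
        dA <- matrix(0, n, M)
        for (j in seq_len(M)) {
          dA[, j] <- rowSums(dhh * fw$Hn[[j]])
          dHn[[j]] <- dHn[[j]] + a[, j] * dhh
        }
        dS <- a * (dA - rowSums(a * dA))
        dHWi <- matrix(0, n, d)
        for (j in seq_len(M)) {
          dHWi <- dHWi + dS[, j] * fw$Hn[[j]]
          dHn[[j]] <- dHn[[j]] + dS[, j] * HWk[[i]]
        }
        g$Wa[[k]] <- g$Wa[[k]] + crossprod(fw$Hn[[i]], dHWi)
        dHn[[i]] <- dHn[[i]] + dHWi %*% t(Wa)
      }
    }
  } else {
    for (m in seq_len(M)) dHn[[m]] <- dHn[[m]] + dhhat[[m]]
  }

  # reconstruction backward (fused kernel: loss gradient w.r.t. decoder and
  # embedding in one pass)
  if (cfg$lambda_rec > 0) {
    g$decoders <- vector("list", M)
    for (m in seq_len(M)) {
      dec <- model$params$decoders[[m]]
      r <- cpp_rec_loss(fw$Hn[[m]], dec$Wd, dec$bd, views$X[[m]],
                        views$mask[[m]], cfg$lambda_rec / cfg$M, TRUE)
      g$decoders[[m]] <- list(Wd = r$dWd, bd = drop(r$dbd))
      dHn[[m]] <- dHn[[m]] + r$dHn
    }
  }

  # alignment backward
  if (cfg$lambda_align > 0 && M >= 2L) {
    Hu <- align_inputs(fw$Hn, cfg$normalize_before_align)
    du <- lapply(seq_len(M), function(m) matrix(0, n, d))
    for (i in seq_len(M - 1L)) for (j in (i + 1L):M) {
      w <- present[, i] * present[, j]
      diff <- Hu$u[[i]] - Hu$u[[j]]
      dd <- cfg$lambda_align * 2 * w * diff / n
      du[[i]] <- du[[i]] + dd
      du[[j]] <- du[[j]] - dd
    }
    for (m in seq_len(M)) {
      if (cfg$normalize_before_align) {
        u <- Hu$u[[m]]
        dHn[[m]] <- dHn[[m]] + (du[[m]] - u * rowSums(du[[m]] * u)) / Hu$nrm[[m]]
      } else {
        dHn[[m]] <- dHn[[m]] + du[[m]]
      }
    }
  }

  # embedding standardization backward (stats are constants), then encoders
  g$encoders <- vector("list", M)
  for (m in seq_len(M)) {
    st <- model$emb_stats[[m]]
    dh <- sweep(dHn[[m]] * present[, m], 2L, st$sd, "/")
    g$encoders[[m]] <- encoder_backward(dh, fw$cache$enc$caches[[m]],
                                        model$params$encoders[[m]])
  }
  g
}
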