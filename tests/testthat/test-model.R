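# Full-model assembly: the batched training path must agree with the
# single-sample reference operations, and every analytic gradient must match
# finite differences.

test_that("the batched forward pass composes the reference operations exactly", {
  prep <- tiny_prep()
  for (wiring in list(list(stage = "gcn", head = "F"),
                      list(stage = "encoder", head = "concat"))) {
    model <- tiny_model(n_heads = 2L, dcmls_stage = wiring$stage,
                        head_input = wiring$head)
    views <- amfn:::batch_to_views(prep$train)
    views$present[1, 2] <- 0 # exercise the masking path
    model <- amfn:::refit_emb_stats(model, views)
    fw <- amfn:::model_forward(model, views, train = FALSE)

    d <- model$cfg$d; M <- model$cfg$M
    for (s in c(1L, 2L, 5L)) {
      pres <- views$present[s, ]
      h <- do.call(rbind, lapply(seq_len(M), function(m) {
        if (pres[m] == 0) return(rep(0, d))
        encode(matrix(views$X[[m]][s, ], model$cfg$channels[m]), m, model)
      }))
      hn <- do.call(rbind, lapply(seq_len(M), function(m) {
        st <- model$emb_stats[[m]]
        ((h[m, ] - st$mean) / st$sd) * pres[m]
      }))
      att <- cross_modal_attention(hn, pres,
                                   list(Wa = model$params$Wa,
                                        proj = model$params$proj))
      A <- build_modality_graph(hn, pres,
                                clamp = model$cfg$similarity_clamp)
      HL <- gcn_propagate(att$h_att, A, list(W = model$params$gcn,
                                             residual = TRUE))
      z <- concat_graph_embedding(HL)
      hsrc <- if (wiring$stage == "gcn") HL else hn
      gt <- adaptive_gate(hsrc, list(w = model$params$gate), pres)
      cf <- context_fusion(gt$h_gated, pres, model$params$query)
      u <- switch(wiring$head, F = cf$f, concat = c(z, cf$f))
      yhat <- sum(u * model$params$head_W) + model$params$head_b

      expect_equal(fw$Z[s, ], z, tolerance = 1e-8)
      expect_equal(fw$gamma[s, ], gt$gamma, tolerance = 1e-8)
      expect_equal(fw$beta[s, ], cf$beta, tolerance = 1e-8)
      expect_equal(fw$Fv[s, ], cf$f, tolerance = 1e-8)
      expect_equal(fw$yhat[s], yhat, tolerance = 1e-8)
    }
  }
})

fd_check <- function(model, views, get, set, analytic, n_coord = 4,
                     eps = 1e-5) {
  p <- get(model)
  idx <- sample(length(p), min(n_coord, length(p)))
  for (i in idx) {
    m1 <- set(model, replace(p, i, p[i] + eps))
    m2 <- set(model, replace(p, i, p[i] - eps))
    l1 <- amfn:::model_forward(m1, views, train = FALSE)$loss$total
    l2 <- amfn:::model_forward(m2, views, train = FALSE)$loss$total
    gn <- (l1 - l2) / (2 * eps)
    expect_equal(analytic[i], gn, tolerance = 1e-4)
  }
}

test_that("analytic gradients match finite differences on every parameter group", {
  set.seed(31)
  prep <- tiny_prep()
  # zero GCN weights make the detached-adjacency path inert so the remaining
  # gradient is exact, not just unbiased
  model <- tiny_model(n_heads = 2L)
  model$params$gcn <- lapply(model$params$gcn, function(W) W * 0)
  views <- amfn:::batch_to_views(prep$train)
  views$present[2, 3] <- 0
  model <- amfn:::refit_emb_stats(model, views)
  fw <- amfn:::model_forward(model, views, train = FALSE)
  g <- amfn:::model_backward(model, views, fw)

  fd_check(model, views, function(m) m$params$head_W,
           function(m, v) { m$params$head_W <- matrix(v, ncol = 1); m },
           g$head_W)
  fd_check(model, views, function(m) m$params$query,
           function(m, v) { m$params$query <- v; m }, g$query)
  fd_check(model, views, function(m) m$params$gate,
           function(m, v) { m$params$gate <- matrix(v, 3); m }, g$gate)
  fd_check(model, views, function(m) m$params$Wa[[2]],
           function(m, v) { m$params$Wa[[2]] <- matrix(v, 6); m }, g$Wa[[2]])
  fd_check(model, views, function(m) m$params$proj,
           function(m, v) { m$params$proj <- matrix(v, 12); m }, g$proj)
  fd_check(model, views, function(m) m$params$encoders[[1]]$W1,
           function(m, v) { m$params$encoders[[1]]$W1 <- matrix(v, 10); m },
           g$encoders[[1]]$W1)
  fd_check(model, views, function(m) m$params$encoders[[2]]$W2,
           function(m, v) { m$params$encoders[[2]]$W2 <- matrix(v, 30); m },
           g$encoders[[2]]$W2)
  fd_check(model, views, function(m) m$params$decoders[[1]]$Wd,
           function(m, v) { m$params$decoders[[1]]$Wd <- matrix(v, 6); m },
           g$decoders[[1]]$Wd)
})

test_that("GCN weight gradients match finite differences", {
  # perturbing GCN weights leaves the embeddings, and hence the detached
  # adjacency, unchanged, so these gradients are exact even though gradient
  # flow through A is stopped
  set.seed(32)
  prep <- tiny_prep()
  model <- tiny_model(lambda_align = 0, lambda_rec = 0)
  views <- amfn:::batch_to_views(prep$train)
  model <- amfn:::refit_emb_stats(model, views)
  fw <- amfn:::model_forward(model, views, train = FALSE)
  g <- amfn:::model_backward(model, views, fw)
  fd_check(model, views, function(m) m$params$gcn[[1]],
           function(m, v) { m$params$gcn[[1]] <- matrix(v, 6); m },
           g$gcn[[1]])
  fd_check(model, views, function(m) m$params$gcn[[2]],
           function(m, v) { m$params$gcn[[2]] <- matrix(v, 6); m },
           g$gcn[[2]])
})

test_that("GRU encoder gradients match finite differences", {
  set.seed(33)
  C <- 2L; win <- 12L; d <- 4L; n <- 3L
  enc <- amfn:::with_seed(3, amfn:::init_encoder("gru", C, win, d))
  X <- matrix(rnorm(n * C * win), n, C * win)
  R <- matrix(rnorm(n * d), n, d)
  fw <- amfn:::encoder_forward(X, enc, "gru", C)
  g <- amfn:::encoder_backward(R, fw$cache, enc)
  for (nm in c("Uz", "Wr", "bc", "Wl")) {
    p <- enc[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      eps <- 1e-5
      e2 <- enc; e2[[nm]] <- replace(p, i, p[i] + eps)
      l1 <- sum(amfn:::encoder_forward(X, e2, "gru", C)$h * R)
      e2[[nm]] <- replace(p, i, p[i] - eps)
      l2 <- sum(amfn:::encoder_forward(X, e2, "gru", C)$h * R)
      expect_equal(g[[nm]][i], (l1 - l2) / (2 * eps), tolerance = 1e-5)
    }
  }
})

test_that("focal-loss gradients match finite differences", {
  set.seed(34)
  ds <- tiny_dataset(task = "binary")
  prep <- tiny_prep(ds)
  model <- tiny_model(task = "binary", task_loss = "focal", focal_gamma = 2)
  views <- amfn:::batch_to_views(prep$train)
  model <- amfn:::refit_emb_stats(model, views)
  fw <- amfn:::model_forward(model, views, train = FALSE)
  g <- amfn:::model_backward(model, views, fw)
  fd_check(model, views, function(m) m$params$head_W,
           function(m, v) { m$params$head_W <- matrix(v, ncol = 1); m },
           g$head_W)
})

test_that("a sample with every modality absent is rejected", {
  prep <- tiny_prep()
  model <- tiny_model()
  views <- amfn:::batch_to_views(prep$train)
  views$present[1, ] <- 0
  expect_error(amfn:::model_forward(model, views), "absent")
})

test_that("ablated variants change exactly the advertised mechanism", {
  prep <- tiny_prep()
  views <- amfn:::batch_to_views(prep$train)
  m_gate <- tiny_model(ablate = "gating")
  fw <- amfn:::model_forward(amfn:::refit_emb_stats(m_gate, views), views)
  expect_true(all(fw$gamma == views$present))
  m_att <- tiny_model(ablate = "attention")
  expect_null(m_att$params$Wa)
  fw2 <- amfn:::model_forward(amfn:::refit_emb_stats(m_att, views), views)
  expect_equal(fw2$cache$hhat, fw2$Hn)
  expect_error(tiny_model(ablate = "spurious"), "unknown ablation")
})
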