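# Fusion core: bilinear attention, similarity graph, GCN propagation,
# graph-level concatenation. Brute-force double-loop oracles are written
# independently of the implementation.

naive_attention <- function(h, present, Wa) {
  M <- nrow(h)
  alpha <- matrix(0, M, M)
  for (i in seq_len(M)) {
    if (present[i] == 0) next
    s <- rep(-Inf, M)
    for (j in seq_len(M)) {
      if (present[j] == 1) s[j] <- drop(h[i, ] %*% Wa %*% h[j, ])
    }
    e <- exp(s - max(s[is.finite(s)]))
    e[!is.finite(s)] <- 0
    alpha[i, ] <- e / sum(e)
  }
  hatt <- matrix(0, M, ncol(h))
  for (i in seq_len(M)) for (j in seq_len(M)) {
    hatt[i, ] <- hatt[i, ] + alpha[i, j] * h[j, ]
  }
  list(alpha = alpha, h_att = hatt)
}

naive_graph <- function(h, present, clamp = 1e-8) {
  M <- nrow(h)
  S <- matrix(0, M, M)
  for (i in seq_len(M)) for (j in seq_len(M)) {
    S[i, j] <- sum(h[i, ] * h[j, ]) /
      (sqrt(sum(h[i, ]^2)) * sqrt(sum(h[j, ]^2)))
  }
  S[S < clamp] <- clamp
  A <- matrix(0, M, M)
  for (i in seq_len(M)) {
    if (present[i] == 0) next
    z <- sum(S[i, present == 1])
    for (j in seq_len(M)) if (present[j] == 1) A[i, j] <- S[i, j] / z
  }
  A
}

test_that("equal embeddings give exactly uniform attention", {
  M <- 4; d <- 8
  h <- matrix(rep(rnorm(d), each = M), M, d)
  Wa <- matrix(rnorm(d * d), d, d)
  out <- cross_modal_attention(h, rep(1, M), list(Wa = list(Wa)))
  expect_equal(out$alpha, matrix(1 / M, M, M))
  expect_equal(out$h_att, h, tolerance = 1e-12)
})

test_that("zero bilinear matrix gives uniform attention and mean aggregation", {
  set.seed(4)
  M <- 3; d <- 5
  h <- matrix(rnorm(M * d), M, d)
  out <- cross_modal_attention(h, rep(1, M), list(Wa = list(matrix(0, d, d))))
  expect_equal(out$alpha, matrix(1 / M, M, M))
  for (i in 1:M) expect_equal(out$h_att[i, ], colMeans(h), tolerance = 1e-12)
})

test_that("attention matches the double-loop oracle on random instances", {
  set.seed(11)
  for (rep in 1:25) {
    M <- sample(2:6, 1); d <- sample(2:16, 1)
    h <- matrix(rnorm(M * d), M, d)
    present <- rep(1, M)
    if (M > 2) present[sample(M, sample(0:(M - 2), 1))] <- 0
    Wa <- matrix(rnorm(d * d, sd = 0.5), d, d)
    ours <- cross_modal_attention(h * present, present, list(Wa = list(Wa)))
    ref <- naive_attention(h * present, present, Wa)
    expect_equal(ours$alpha, ref$alpha, tolerance = 1e-6)
    expect_equal(ours$h_att[present == 1, ], ref$h_att[present == 1, ],
                 tolerance = 1e-6)
  }
})

test_that("attention rows over present modalities are probability vectors", {
  set.seed(12)
  for (rep in 1:20) {
    M <- sample(2:6, 1); d <- sample(2:32, 1)
    h <- matrix(rnorm(M * d), M, d)
    present <- rep(1, M)
    out <- cross_modal_attention(h, present,
                                 list(Wa = lapply(1:2, function(k)
                                   matrix(rnorm(d * d), d, d)),
                                   proj = matrix(rnorm(2 * d * d), 2 * d, d)))
    expect_true(all(out$alpha >= 0))
    expect_equal(rowSums(out$alpha), rep(1, M), tolerance = 1e-6)
  }
})

test_that("all modalities absent is an error", {
  h <- matrix(0, 3, 4)
  expect_error(cross_modal_attention(h, c(0, 0, 0),
                                     list(Wa = list(diag(4)))), "absent")
  expect_error(context_fusion(h, c(0, 0, 0), rnorm(4)), "absent")
  expect_error(build_modality_graph(h, c(0, 0, 0)), "absent")
})

test_that("orthogonal embeddings give a near-identity adjacency", {
  h <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  A <- build_modality_graph(h, c(1, 1))
  expect_equal(diag(A), rep(1, 2), tolerance = 1e-6)
  expect_lt(max(A[row(A) != col(A)]), 1e-6)
})

test_that("identical embeddings give the uniform adjacency", {
  h <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  A <- build_modality_graph(h, rep(1, 4))
  expect_equal(A, matrix(1 / 4, 4, 4), tolerance = 1e-9)
})

test_that("adjacency matches the loop oracle and rows sum to one", {
  set.seed(13)
  for (rep in 1:25) {
    M <- sample(2:5, 1); d <- sample(2:16, 1)
    h <- matrix(rnorm(M * d), M, d)
    A <- build_modality_graph(h, rep(1, M))
    expect_equal(A, naive_graph(h, rep(1, M)), tolerance = 1e-9)
    expect_equal(rowSums(A), rep(1, M), tolerance = 1e-9)
    expect_true(all(A >= 0))
  }
})

test_that("zero-norm embeddings trigger the clamp path with a warning", {
  h <- rbind(rep(0, 4), c(1, 2, 3, 4))
  expect_warning(A <- build_modality_graph(h, c(1, 1)), "zero-norm")
  expect_equal(rowSums(A), rep(1, 2), tolerance = 1e-9)
})

test_that("softmax adjacency mode also yields a stochastic matrix", {
  set.seed(14)
  h <- matrix(rnorm(12), 3, 4)
  A <- build_modality_graph(h, rep(1, 3), mode = "softmax")
  expect_equal(rowSums(A), rep(1, 3), tolerance = 1e-9)
  expect_true(all(A > 0))
})

test_that("identity propagation doubles per residual layer", {
  # relu is inactive on nonnegative input, so each layer maps H to 2H
  H0 <- matrix(abs(rnorm(12)), 3, 4)
  out1 <- gcn_propagate(H0, diag(3), list(W = list(diag(4)), residual = TRUE))
  expect_equal(out1, 2 * H0, tolerance = 1e-12)
  out2 <- gcn_propagate(H0, diag(3), list(W = list(diag(4), diag(4)),
                                          residual = TRUE))
  expect_equal(out2, 4 * H0, tolerance = 1e-12)
})

test_that("a single GCN layer matches the triple-loop product oracle", {
  set.seed(15)
  for (rep in 1:25) {
    M <- sample(2:6, 1); d <- sample(2:8, 1)
    H <- matrix(rnorm(M * d), M, d)
    A <- matrix(runif(M * M), M, M); A <- A / rowSums(A)
    W <- matrix(rnorm(d * d), d, d)
    out <- gcn_propagate(H, A, list(W = list(W), residual = FALSE,
                                    activation = "identity"))
    ref <- matrix(0, M, d)
    for (i in seq_len(M)) for (f in seq_len(d)) {
      for (j in seq_len(M)) for (e in seq_len(d)) {
        ref[i, f] <- ref[i, f] + A[i, j] * H[j, e] * W[e, f]
      }
    }
    expect_equal(out, ref, tolerance = 1e-6)
  }
})

test_that("row-stochastic propagation fixes identical rows", {
  A <- matrix(runif(9), 3, 3); A <- A / rowSums(A)
  H <- matrix(rep(c(1, -2, 3, 0.5), each = 3), 3, 4)
  expect_equal(A %*% H, H, tolerance = 1e-12)
  out <- gcn_propagate(H, A, list(W = list(diag(4)), residual = FALSE,
                                  activation = "identity"))
  expect_equal(out, H, tolerance = 1e-12)
})

test_that("graph embedding concatenates rows in fixed modality order", {
  H <- matrix(1:12, 3, 4)
  z <- concat_graph_embedding(H)
  expect_length(z, 12)
  expect_equal(z[1:4], H[1, ])
  expect_equal(z[9:12], H[3, ])
  perm <- c(2, 3, 1)
  zp <- concat_graph_embedding(H[perm, ])
  expect_equal(zp[1:4], H[2, ])
  expect_equal(concat_graph_embedding(matrix(0, 3, 128)), rep(0, 384))
})

test_that("embedding length follows M times d", {
  expect_length(concat_graph_embedding(matrix(rnorm(3 * 128), 3, 128)), 384)
})
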