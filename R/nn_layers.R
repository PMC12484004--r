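# Low-level neural layers with hand-derived backward passes. All layers use
# the channel-fastest layout: a batch of multichannel series is an
# n x (C * L) matrix whose column (t - 1) * C + c holds channel c at step t.
# Gradient correctness is enforced by finite-difference tests.

xavier_init <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

kaiming_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

conv1d_out_len <- function(L, K = 5L, S = 2L) (L - K) %/% S + 1L

# In the flat layout a kernel window is a contiguous block of K * C
# columns, so the strided convolution is a sequence of small GEMMs on column
# views; the loops live in RcppArmadillo (src/conv1d.cpp), which is where
# all the training time goes.

dropout_forward <- function(X, p, train) {
  if (!train || p <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix((stats::runif(length(X)) >= p) / (1 - p), nrow(X), ncol(X))
  list(Y = X * mask, mask = mask)
}

# ---- encoder construction --------------------------------------------------

init_encoder <- function(type, C, win, d) {
  enc <- list(n_channels = C, win = win)
  if (type == "tcn") {
    if (conv1d_out_len(conv1d_out_len(win)) < 1L) {
      stop_amfn("window too short for the two-layer convolutional encoder")
    }
    enc$W1 <- kaiming_init(C * 5L, d); enc$b1 <- numeric(d)
    enc$W2 <- kaiming_init(d * 5L, d); enc$b2 <- numeric(d)
    enc$Wl <- xavier_init(d, d); enc$bl <- numeric(d)
  } else if (type == "gru") {
    for (g in c("z", "r", "c")) {
      enc[[paste0("U", g)]] <- xavier_init(C, d)
      enc[[paste0("W", g)]] <- xavier_init(d, d)
      enc[[paste0("b", g)]] <- numeric(d)
    }
    enc$Wl <- xavier_init(d, d); enc$bl <- numeric(d)
  } else if (type == "mean") {
    enc$Wl <- xavier_init(C, d); enc$bl <- numeric(d)
  } else stop_amfn(sprintf("unknown encoder type '%s'", type))
  enc
}

encoder_param_names <- function(type) {
  switch(type,
         tcn = c("W1", "b1", "W2", "b2", "Wl", "bl"),
         gru = c("Uz", "Wz", "bz", "Ur", "Wr", "br", "Uc", "Wc", "bc", "Wl", "bl"),
         mean = c("Wl", "bl"))
}

encoder_forward <- function(X, enc, type, C, train = FALSE, dropout = 0) {
  n <- nrow(X)
  if (type == "tcn") {
    tr <- cpp_tcn_forward(X, enc$W1, enc$b1, enc$W2, enc$b2, C, 5L, 2L)
    dr <- dropout_forward(tr$P, dropout, train)
    h <- dr$Y %*% enc$Wl + rep(enc$bl, each = n)
    list(h = h, cache = list(type = type, X = X, R1 = tr$R1, R2 = tr$R2,
                             drop_mask = dr$mask, lin_in = dr$Y))
  } else if (type == "mean") {
    P <- matrix(0, n, C)
    L <- ncol(X) %/% C
    for (c in seq_len(C)) {
      P[, c] <- rowMeans(X[, seq.int(c, by = C, length.out = L),
                           drop = FALSE])
    }
    h <- P %*% enc$Wl + rep(enc$bl, each = n)
    list(h = h, cache = list(type = type, lin_in = P))
  } else if (type == "gru") {
    n <- nrow(X); d <- ncol(enc$Wl)
    L <- ncol(X) %/% C
    h <- matrix(0, n, d)
    steps <- vector("list", L)
    for (t in seq_len(L)) {
      x <- X[, ((t - 1L) * C + 1L):(t * C), drop = FALSE]
      z <- sigmoid(x %*% enc$Uz + h %*% enc$Wz + rep(enc$bz, each = n))
      r <- sigmoid(x %*% enc$Ur + h %*% enc$Wr + rep(enc$br, each = n))
      cc <- tanh(x %*% enc$Uc + (r * h) %*% enc$Wc + rep(enc$bc, each = n))
      steps[[t]] <- list(z = z, r = r, c = cc, h_prev = h)
      h <- (1 - z) * cc + z * h
    }
    dr <- dropout_forward(h, dropout, train)
    out <- dr$Y %*% enc$Wl + rep(enc$bl, each = n)
    list(h = out, cache = list(type = type, steps = steps, L = L, C = C,
                               drop_mask = dr$mask, lin_in = dr$Y, X = X))
  } else stop_amfn("unknown encoder type")
}

encoder_backward <- function(dh, cache, enc) {
  n <- nrow(dh)
  g <- list()
  g$Wl <- crossprod(cache$lin_in, dh)
  g$bl <- colSums(dh)
  dpre <- dh %*% t(enc$Wl)
  if (!is.null(cache$drop_mask)) dpre <- dpre * cache$drop_mask
  if (cache$type == "tcn") {
    bk <- cpp_tcn_backward(cache$X, cache$R1, cache$R2, enc$W1, enc$W2,
                           dpre, enc$n_channels, 5L, 2L)
    g$W1 <- bk$dW1; g$b1 <- drop(bk$db1)
    g$W2 <- bk$dW2; g$b2 <- drop(bk$db2)
  } else if (cache$type == "gru") {
    for (nm in c("Uz", "Wz", "bz", "Ur", "Wr", "br", "Uc", "Wc", "bc")) {
      g[[nm]] <- if (grepl("^b", nm)) numeric(length(enc[[nm]])) else
        matrix(0, nrow(enc[[nm]]), ncol(enc[[nm]]))
    }
    dhh <- dpre
    C <- cache$C
    for (t in rev(seq_len(cache$L))) {
      st <- cache$steps[[t]]
      x <- cache$X[, ((t - 1L) * C + 1L):(t * C), drop = FALSE]
      dz <- dhh * (st$h_prev - st$c)
      dc <- dhh * (1 - st$z)
      dh_prev <- dhh * st$z
      dac <- dc * (1 - st$c^2)
      g$Uc <- g$Uc + crossprod(x, dac)
      g$Wc <- g$Wc + crossprod(st$r * st$h_prev, dac)
      g$bc <- g$bc + colSums(dac)
      drh <- dac %*% t(enc$Wc)
      dr <- drh * st$h_prev
      dh_prev <- dh_prev + drh * st$r
      daz <- dz * st$z * (1 - st$z)
      g$Uz <- g$Uz + crossprod(x, daz)
      g$Wz <- g$Wz + crossprod(st$h_prev, daz)
      g$bz <- g$bz + colSums(daz)
      dh_prev <- dh_prev + daz %*% t(enc$Wz)
      dar <- dr * st$r * (1 - st$r)
      g$Ur <- g$Ur + crossprod(x, dar)
      g$Wr <- g$Wr + crossprod(st$h_prev, dar)
      g$br <- g$br + colSums(dar)
      dh_prev <- dh_prev + dar %*% t(enc$Wr)
      dhh <- dh_prev
    }
  }
  # mean encoder: only the linear layer is trainable
  g
}
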