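// Temporal-convolution encoder kernels. Batches use the flat
// channel-fastest layout: X is n x (C * L) with column (t - 1) * C + c
// holding channel c at step t, so a layer-1 kernel window is a contiguous
// block of K * C columns. Layer activations are kept stacked
// ((n * Lo) x d, row t * n + i = sample i at step t). Layer 2 materializes
// its im2col matrix once per pass and runs a single GEMM. Large arguments
// are wrapped as no-copy views.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int out_len(int L, int K, int S) { return (L - K) / S + 1; }

static mat view(const Rcpp::NumericMatrix& m) {
  return mat(const_cast<double*>(m.begin()), m.nrow(), m.ncol(), false, true);
}

static void relu_inplace(mat& A) {
  double* p = A.memptr();
  const uword n = A.n_elem;
  for (uword i = 0; i < n; ++i) {
    if (p[i] < 0) p[i] = 0;
  }
}

// Zero entries of dA wherever the post-relu activation A is zero.
static void relu_mask(mat& dA, const mat& A) {
  double* p = dA.memptr();
  const double* a = A.memptr();
  const uword n = dA.n_elem;
  for (uword i = 0; i < n; ++i) {
    if (a[i] <= 0) p[i] = 0;
  }
}

// im2col over stacked layer-1 activations: patch rows for output step t are
// the K row blocks t*S .. t*S+K-1.
static mat im2col_stacked(const mat& R1, int n, int K, int S, int Lo2) {
  const int d = R1.n_cols;
  mat Xp(n * Lo2, d * K);
  for (int t = 0; t < Lo2; ++t) {
    for (int k = 0; k < K; ++k) {
      Xp.submat(t * n, k * d, (t + 1) * n - 1, (k + 1) * d - 1) =
        R1.rows((t * S + k) * n, (t * S + k + 1) * n - 1);
    }
  }
  return Xp;
}

// Whole two-layer conv encoder trunk (conv -> relu -> conv -> relu ->
// global mean pool). Activations are returned stacked for the backward
// pass.
// [[Rcpp::export]]
Rcpp::List cpp_tcn_forward(const Rcpp::NumericMatrix& Xr,
                           const Rcpp::NumericMatrix& W1r,
                           const arma::vec& b1,
                           const Rcpp::NumericMatrix& W2r,
                           const arma::vec& b2, int C, int K, int S) {
  const mat X = view(Xr), W1 = view(W1r), W2 = view(W2r);
  const int n = X.n_rows;
  const int d = W1.n_cols;
  const int L = X.n_cols / C;
  const int Lo1 = out_len(L, K, S);
  const int Lo2 = out_len(Lo1, K, S);

  mat R1(n * Lo1, d);
  for (int t = 0; t < Lo1; ++t) {
    R1.rows(t * n, (t + 1) * n - 1) =
      X.cols(t * S * C, t * S * C + C * K - 1) * W1;
  }
  R1.each_row() += b1.t();
  relu_inplace(R1);

  mat R2 = im2col_stacked(R1, n, K, S, Lo2) * W2;
  R2.each_row() += b2.t();
  relu_inplace(R2);

  mat P(n, d, fill::zeros);
  for (int t = 0; t < Lo2; ++t) P += R2.rows(t * n, (t + 1) * n - 1);
  P /= Lo2;
  return Rcpp::List::create(Rcpp::Named("R1") = R1,
                            Rcpp::Named("R2") = R2,
                            Rcpp::Named("P") = P);
}

// [[Rcpp::export]]
Rcpp::List cpp_tcn_backward(const Rcpp::NumericMatrix& Xr,
                            const Rcpp::NumericMatrix& R1r,
                            const Rcpp::NumericMatrix& R2r,
                            const Rcpp::NumericMatrix& W1r,
                            const Rcpp::NumericMatrix& W2r,
                            const Rcpp::NumericMatrix& dPr,
                            int C, int K, int S) {
  const mat X = view(Xr), R1 = view(R1r), R2 = view(R2r);
  const mat W1 = view(W1r), W2 = view(W2r), dP = view(dPr);
  const int n = X.n_rows;
  const int d = W1.n_cols;
  const int Lo1 = R1.n_rows / n;
  const int Lo2 = R2.n_rows / n;

  // pool backward + relu mask
  mat dR2(n * Lo2, d);
  const mat dPs = dP / Lo2;
  for (int t = 0; t < Lo2; ++t) dR2.rows(t * n, (t + 1) * n - 1) = dPs;
  relu_mask(dR2, R2);

  // conv2 backward
  mat Xp2 = im2col_stacked(R1, n, K, S, Lo2);
  mat dW2 = Xp2.t() * dR2;
  vec db2 = sum(dR2, 0).t();
  mat dXp2 = dR2 * W2.t();
  mat dR1(n * Lo1, d, fill::zeros);
  for (int t = 0; t < Lo2; ++t) {
    for (int k = 0; k < K; ++k) {
      dR1.rows((t * S + k) * n, (t * S + k + 1) * n - 1) +=
        dXp2.submat(t * n, k * d, (t + 1) * n - 1, (k + 1) * d - 1);
    }
  }
  relu_mask(dR1, R1);

  // conv1 backward (input gradient not needed)
  mat dW1(C * K, d, fill::zeros);
  for (int t = 0; t < Lo1; ++t) {
    dW1 += X.cols(t * S * C, t * S * C + C * K - 1).t() *
      dR1.rows(t * n, (t + 1) * n - 1);
  }
  vec db1 = sum(dR1, 0).t();
  return Rcpp::List::create(Rcpp::Named("dW1") = dW1,
                            Rcpp::Named("db1") = db1,
                            Rcpp::Named("dW2") = dW2,
                            Rcpp::Named("db2") = db2);
}

// Masked reconstruction loss of one modality's linear decoder, fused with
// its gradients: Xhat = Hn * Wd + bd; the squared error is averaged over
// observed cells only. Gradients are already multiplied by `scale` (the
// caller folds in lambda_rec / M).
// [[Rcpp::export]]
Rcpp::List cpp_rec_loss(const Rcpp::NumericMatrix& Hnr,
                        const Rcpp::NumericMatrix& Wdr,
                        const arma::vec& bd,
                        const Rcpp::NumericMatrix& Xr,
                        const Rcpp::NumericMatrix& maskr, double scale,
                        bool need_grad) {
  const mat Hn = view(Hnr), Wd = view(Wdr), X = view(Xr), mask = view(maskr);
  mat Xhat = Hn * Wd;
  Xhat.each_row() += bd.t();
  mat diff = (Xhat - X) % mask;
  double denom = accu(mask);
  if (denom < 1.0) denom = 1.0;
  double loss = accu(square(diff)) / denom;
  if (!need_grad) {
    return Rcpp::List::create(Rcpp::Named("loss") = loss);
  }
  mat dXhat = diff * (2.0 * scale / denom);
  mat dHn = dXhat * Wd.t();
  mat dWd = Hn.t() * dXhat;
  vec dbd = sum(dXhat, 0).t();
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("dHn") = dHn,
                            Rcpp::Named("dWd") = dWd,
                            Rcpp::Named("dbd") = dbd);
}
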