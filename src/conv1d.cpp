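#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Causal dilated 1-D convolution over a batch of zero-padded sequences.
//
// The batch is stored as a single (B*T) x C matrix whose row index is
// b + B*t (sequence b, time step t, both 0-based).  A kernel tap kappa with
// dilation d reads the input shifted kappa*d steps into the past; shifts that
// fall before t = 0 read implicit zeros, which is exactly left zero-padding.
// This layout turns each tap into one dense GEMM on contiguous rows.

// [[Rcpp::export(name = ".convCausalForward")]]
arma::mat convCausalForward(const arma::mat& X, int B, int T,
                            const arma::mat& W, const arma::rowvec& bias,
                            int dilation) {
  const int Cin = X.n_cols;
  const int k = W.n_rows / Cin;
  mat Y(B * T, W.n_cols);
  Y.each_row() = bias;
  for (int kap = 0; kap < k; ++kap) {
    const int s = kap * dilation;
    if (s >= T) continue;
    const int n = B * (T - s);
    Y.rows(B * s, B * T - 1) +=
        X.rows(0, n - 1) * W.rows(kap * Cin, (kap + 1) * Cin - 1);
  }
  return Y;
}

// Gradients of the causal convolution: dX, dW and db from upstream dY.
// [[Rcpp::export(name = ".convCausalBackward")]]
Rcpp::List convCausalBackward(const arma::mat& X, const arma::mat& dY,
                              int B, int T, const arma::mat& W, int dilation) {
  const int Cin = X.n_cols;
  const int k = W.n_rows / Cin;
  mat dX(size(X), fill::zeros);
  mat dW(size(W), fill::zeros);
  rowvec db = sum(dY, 0);
  for (int kap = 0; kap < k; ++kap) {
    const int s = kap * dilation;
    if (s >= T) continue;
    const int n = B * (T - s);
    dW.rows(kap * Cin, (kap + 1) * Cin - 1) =
        X.rows(0, n - 1).t() * dY.rows(B * s, B * T - 1);
    dX.rows(0, n - 1) +=
        dY.rows(B * s, B * T - 1) * W.rows(kap * Cin, (kap + 1) * Cin - 1).t();
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
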