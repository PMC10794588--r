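#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fused forward/backward for one residual TCN block:
//   conv1 -> ReLU -> dropout -> conv2 -> ReLU -> dropout, plus a residual
//   connection (1x1 convolution when the channel count changes), then ReLU.
// Dropout masks are drawn from R's RNG so runs stay seed-reproducible.

static mat convFwd(const mat& X, int B, int T, const mat& W,
                   const rowvec& bias, int dilation) {
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

static void convBwd(const mat& X, const mat& dY, int B, int T, const mat& W,
                    int dilation, mat& dX, mat& dW, rowvec& db) {
  const int Cin = X.n_cols;
  const int k = W.n_rows / Cin;
  dX.zeros(X.n_rows, X.n_cols);
  dW.zeros(W.n_rows, W.n_cols);
  db = sum(dY, 0);
  for (int kap = 0; kap < k; ++kap) {
    const int s = kap * dilation;
    if (s >= T) continue;
    const int n = B * (T - s);
    dW.rows(kap * Cin, (kap + 1) * Cin - 1) =
        X.rows(0, n - 1).t() * dY.rows(B * s, B * T - 1);
    dX.rows(0, n - 1) +=
        dY.rows(B * s, B * T - 1) * W.rows(kap * Cin, (kap + 1) * Cin - 1).t();
  }
}

static mat drawMask(int n, int m, double rate) {
  mat mask(n, m);
  const double keep = 1.0 - rate;
  double* p = mask.memptr();
  const int len = n * m;
  for (int i = 0; i < len; ++i)
    p[i] = (unif_rand() < rate) ? 0.0 : 1.0 / keep;
  return mask;
}

// [[Rcpp::export(name = ".tcnBlockForward")]]
Rcpp::List tcnBlockForward(const arma::mat& M, int B, int T,
                           const arma::mat& W1, const arma::rowvec& b1,
                           const arma::mat& W2, const arma::rowvec& b2,
                           Rcpp::Nullable<Rcpp::NumericMatrix> Wd,
                           Rcpp::Nullable<Rcpp::NumericVector> bd,
                           int dilation, double rate, bool training) {
  Rcpp::RNGScope rngScope;
  const bool drop = training && rate > 0.0;
  mat A1 = convFwd(M, B, T, W1, b1, dilation);
  A1.transform([](double v) { return v > 0.0 ? v : 0.0; });
  mat mask1, mask2;
  mat D1 = A1;
  if (drop) {
    mask1 = drawMask(A1.n_rows, A1.n_cols, rate);
    D1 %= mask1;
  }
  mat A2 = convFwd(D1, B, T, W2, b2, dilation);
  A2.transform([](double v) { return v > 0.0 ? v : 0.0; });
  mat D2 = A2;
  if (drop) {
    mask2 = drawMask(A2.n_rows, A2.n_cols, rate);
    D2 %= mask2;
  }
  mat out;
  if (Wd.isNotNull()) {
    mat WdM = Rcpp::as<mat>(Wd.get());
    rowvec bdV = Rcpp::as<rowvec>(bd.get());
    out = M * WdM;
    out.each_row() += bdV;
    out += D2;
  } else {
    out = D2 + M;
  }
  out.transform([](double v) { return v > 0.0 ? v : 0.0; });
  return Rcpp::List::create(
      Rcpp::Named("out") = out, Rcpp::Named("A1") = A1,
      Rcpp::Named("D1") = D1, Rcpp::Named("A2") = A2,
      Rcpp::Named("mask1") = drop ? Rcpp::wrap(mask1) : R_NilValue,
      Rcpp::Named("mask2") = drop ? Rcpp::wrap(mask2) : R_NilValue);
}

// [[Rcpp::export(name = ".tcnBlockBackward")]]
Rcpp::List tcnBlockBackward(const arma::mat& M, int B, int T,
                            const arma::mat& W1, const arma::mat& W2,
                            Rcpp::Nullable<Rcpp::NumericMatrix> Wd,
                            int dilation, const Rcpp::List& cache,
                            const arma::mat& dOut) {
  const mat& out = Rcpp::as<mat>(cache["out"]);
  const mat& A1 = Rcpp::as<mat>(cache["A1"]);
  const mat& D1 = Rcpp::as<mat>(cache["D1"]);
  const mat& A2 = Rcpp::as<mat>(cache["A2"]);
  mat dS = dOut;
  {
    const double* o = out.memptr();
    double* d = dS.memptr();
    const int len = dS.n_elem;
    for (int i = 0; i < len; ++i)
      if (o[i] <= 0.0) d[i] = 0.0;
  }
  mat dA2 = dS;
  if (!Rf_isNull(cache["mask2"])) dA2 %= Rcpp::as<mat>(cache["mask2"]);
  {
    const double* a = A2.memptr();
    double* d = dA2.memptr();
    const int len = dA2.n_elem;
    for (int i = 0; i < len; ++i)
      if (a[i] <= 0.0) d[i] = 0.0;
  }
  mat dD1, dW2;
  rowvec db2;
  convBwd(D1, dA2, B, T, W2, dilation, dD1, dW2, db2);
  if (!Rf_isNull(cache["mask1"])) dD1 %= Rcpp::as<mat>(cache["mask1"]);
  {
    const double* a = A1.memptr();
    double* d = dD1.memptr();
    const int len = dD1.n_elem;
    for (int i = 0; i < len; ++i)
      if (a[i] <= 0.0) d[i] = 0.0;
  }
  mat dM, dW1;
  rowvec db1;
  convBwd(M, dD1, B, T, W1, dilation, dM, dW1, db1);
  Rcpp::List grads = Rcpp::List::create(
      Rcpp::Named("W1") = dW1,
      Rcpp::Named("b1") = Rcpp::NumericVector(db1.begin(), db1.end()),
      Rcpp::Named("W2") = dW2,
      Rcpp::Named("b2") = Rcpp::NumericVector(db2.begin(), db2.end()));
  if (Wd.isNotNull()) {
    mat WdM = Rcpp::as<mat>(Wd.get());
    grads.push_back(Rcpp::wrap(mat(M.t() * dS)), "Wd");
    rowvec dbd = sum(dS, 0);
    grads.push_back(Rcpp::NumericVector(dbd.begin(), dbd.end()), "bd");
    dM += dS * WdM.t();
  } else {
    dM += dS;
  }
  return Rcpp::List::create(Rcpp::Named("grads") = grads,
                            Rcpp::Named("dM") = dM);
}
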