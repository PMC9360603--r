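// Hot numeric kernels for the CNN engine: fused im2col convolution +
// batch-norm + ReLU forward and backward. Layouts match the R
// orchestration: batches are row-major in examples (column-major arma
// matrices of N rows), conv activations are (N*P) x F with output
// positions p-major inside columns, and idx is the 1-based im2col column
// map (p-major within each patch element k). Output buffers are
// allocated through Rcpp and borrowed by Armadillo so returns are
// copy-free.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat borrow(NumericMatrix& m) {
  return arma::mat(m.begin(), m.nrow(), m.ncol(), false, true);
}

// Forward pass of one conv block. Returns out (post-activation), and when
// want_cache also Xcol and zn; when batch_stats also mu/var for the
// running-statistics update in R.
// [[Rcpp::export]]
List cpp_layer_fwd(const arma::mat& xp, const arma::ivec& idx,
                   const arma::mat& W, const arma::vec& b,
                   const arma::vec& gamma, const arma::vec& beta,
                   const arma::vec& rmean, const arma::vec& rvar,
                   double eps, int P, bool has_bn, bool batch_stats,
                   bool relu, bool want_cache) {
  const int N = xp.n_rows;
  const int K = W.n_rows;
  const int F = W.n_cols;
  const R_xlen_t NP = static_cast<R_xlen_t>(N) * P;
  NumericMatrix XcolR(NP, K);
  arma::mat Xcol = borrow(XcolR);
  for (int k = 0; k < K; ++k) {
    double* dst = Xcol.colptr(k);
    for (int p = 0; p < P; ++p) {
      const double* src = xp.colptr(idx[p + static_cast<long>(P) * k] - 1);
      std::memcpy(dst + static_cast<long>(p) * N, src, N * sizeof(double));
    }
  }
  NumericMatrix ZR(NP, F);
  arma::mat Z = borrow(ZR);
  Z = Xcol * W;
  Z.each_row() += b.t();
  List res = List::create(_["out"] = ZR);
  if (want_cache) res["Xcol"] = XcolR;
  if (has_bn) {
    arma::rowvec mu, v;
    if (batch_stats) {
      mu = arma::mean(Z, 0);
      Z.each_row() -= mu;
      v = arma::mean(arma::square(Z), 0);
      res["mu"] = mu;
      res["var"] = v;
    } else {
      mu = rmean.t();
      v = rvar.t();
      Z.each_row() -= mu;
    }
    arma::rowvec inv = 1.0 / arma::sqrt(v + eps);
    Z.each_row() %= inv;  // Z now holds the normalized activations zn
    if (want_cache) {
      NumericMatrix znR(NP, F);
      arma::mat zn = borrow(znR);
      zn = Z;
      res["zn"] = znR;
      res["inv"] = inv;
    }
    Z.each_row() %= gamma.t();
    Z.each_row() += beta.t();
  }
  if (relu) {
    double* p = Z.memptr();
    for (arma::uword i = 0; i < Z.n_elem; ++i) if (p[i] < 0) p[i] = 0;
  }
  return res;
}

// Backward pass of one conv block: d is the gradient at the block output
// (overwritten in place), out the cached post-activation (for the ReLU
// mask). Returns parameter gradients and the gradient w.r.t. the padded
// input, as an N x (Hp*Wp*C) matrix.
// [[Rcpp::export]]
List cpp_layer_bwd(NumericMatrix dR, const arma::mat& out,
                   SEXP znS, const arma::rowvec& inv,
                   const arma::vec& gamma, const arma::mat& Xcol,
                   const arma::mat& W, const arma::ivec& idx,
                   int P, int n_padcols, bool has_bn, bool batch_stats,
                   bool relu) {
  arma::mat d = borrow(dR);
  const int K = W.n_rows;
  const int N = d.n_rows / P;
  if (relu) {
    double* dp = d.memptr();
    const double* op = out.memptr();
    for (arma::uword i = 0; i < d.n_elem; ++i) if (op[i] <= 0) dp[i] = 0;
  }
  List res;
  if (has_bn) {
    NumericMatrix znR(znS);
    arma::mat zn = borrow(znR);
    arma::rowvec dgamma = arma::sum(d % zn, 0);
    arma::rowvec dbeta = arma::sum(d, 0);
    res["dgamma"] = dgamma;
    res["dbeta"] = dbeta;
    d.each_row() %= gamma.t();
    if (batch_stats) {
      const double n = static_cast<double>(d.n_rows);
      arma::rowvec s1 = arma::sum(d, 0) / n;
      arma::rowvec s2 = arma::sum(d % zn, 0) / n;
      d.each_row() -= s1;
      arma::mat tmp = zn;
      tmp.each_row() %= s2;
      d -= tmp;
    }
    d.each_row() %= inv;
  }
  res["dW"] = arma::mat(Xcol.t() * d);
  res["db"] = arma::rowvec(arma::sum(d, 0));
  arma::mat dXcol = d * W.t();
  NumericMatrix dxpR(N, n_padcols);
  arma::mat dxp = borrow(dxpR);
  for (int k = 0; k < K; ++k) {
    const double* src = dXcol.colptr(k);
    for (int p = 0; p < P; ++p) {
      double* dst = dxp.colptr(idx[p + static_cast<long>(P) * k] - 1);
      const double* s = src + static_cast<long>(p) * N;
      for (int n = 0; n < N; ++n) dst[n] += s[n];
    }
  }
  res["dxp"] = dxpR;
  return res;
}
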