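// Instance normalization forward/backward on the (H*W) x (C*N) matrix view
// of an activation tensor: each column is one (channel, sample) plane.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List inorm_forward_cpp(const arma::mat& X, const arma::vec& g_rep,
                             const arma::vec& b_rep, double eps) {
  const uword hw = X.n_rows, cn = X.n_cols;
  mat Y(hw, cn), xhat(hw, cn);
  vec sd(cn);
  for (uword c = 0; c < cn; ++c) {
    const double* x = X.colptr(c);
    double m = 0;
    for (uword i = 0; i < hw; ++i) m += x[i];
    m /= hw;
    double v = 0;
    for (uword i = 0; i < hw; ++i) { const double d = x[i] - m; v += d * d; }
    v /= hw;
    const double s = std::sqrt(v + eps);
    sd[c] = s;
    double* xh = xhat.colptr(c);
    double* y = Y.colptr(c);
    const double g = g_rep[c], b = b_rep[c];
    for (uword i = 0; i < hw; ++i) {
      xh[i] = (x[i] - m) / s;
      y[i] = g * xh[i] + b;
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("sd") = sd);
}

// [[Rcpp::export]]
Rcpp::List inorm_backward_cpp(const arma::mat& dY, const arma::mat& xhat,
                              const arma::vec& sd, const arma::vec& g_rep) {
  const uword hw = dY.n_rows, cn = dY.n_cols;
  mat dX(hw, cn);
  vec dg(cn), db(cn);
  for (uword c = 0; c < cn; ++c) {
    const double* dy = dY.colptr(c);
    const double* xh = xhat.colptr(c);
    double* dx = dX.colptr(c);
    const double g = g_rep[c], s = sd[c];
    double m1 = 0, m2 = 0, sg = 0, sb = 0;
    for (uword i = 0; i < hw; ++i) {
      const double dxh = dy[i] * g;
      m1 += dxh;
      m2 += dxh * xh[i];
      sg += dy[i] * xh[i];
      sb += dy[i];
    }
    dg[c] = sg; db[c] = sb;
    m1 /= hw; m2 /= hw;
    for (uword i = 0; i < hw; ++i)
      dx[i] = (dy[i] * g - m1 - xh[i] * m2) / s;
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dX,
                            Rcpp::Named("dgamma") = dg,
                            Rcpp::Named("dbeta") = db);
}
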