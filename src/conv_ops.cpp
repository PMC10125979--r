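// Minimal 2D convolution primitives for the CycleGAN generators and
// discriminators. Two execution paths per conv, chosen by shape:
//   * im2col + BLAS gemm (memcpy-based column build for stride 1);
//   * a direct shifted-submatrix path for stride-1 layers with very few
//     output channels, where building the column matrix costs more than
//     the arithmetic.
// Tensors are single-sample arma::cube (H, W, C); the R layer loops over the
// (small) batch. Weight matrices are (k*k*C_in) x C_out with patch index
// r = kj + k*ki + k*k*c  (ki = row offset, kj = column offset, c = channel).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int reflect_idx(int i, int n) {
  // mirror without repeating the border sample (reflection padding)
  if (i < 0) return -i;
  if (i >= n) return 2 * n - 2 - i;
  return i;
}

static cube pad_cube(const cube& x, int p, int mode) {
  if (p == 0) return x;
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube xp(H + 2 * p, W + 2 * p, C, fill::zeros);
  if (mode == 0) {
    xp.subcube(p, p, 0, p + H - 1, p + W - 1, C - 1) = x;
  } else {
    for (int c = 0; c < C; ++c)
      for (int j = -p; j < W + p; ++j) {
        int js = reflect_idx(j, W);
        for (int i = -p; i < H + p; ++i)
          xp(i + p, j + p, c) = x(reflect_idx(i, H), js, c);
      }
  }
  return xp;
}

// fold padded-region gradients back onto interior positions
static cube unpad_grad(const cube& dxp, int p, int mode, int H, int W) {
  const int C = dxp.n_slices;
  if (p == 0) return dxp;
  cube dx(H, W, C, fill::zeros);
  if (mode == 0) {
    dx = dxp.subcube(p, p, 0, p + H - 1, p + W - 1, C - 1);
  } else {
    for (int c = 0; c < C; ++c)
      for (int j = -p; j < W + p; ++j) {
        int js = reflect_idx(j, W);
        for (int i = -p; i < H + p; ++i)
          dx(reflect_idx(i, H), js, c) += dxp(i + p, j + p, c);
      }
  }
  return dx;
}

static mat im2col(const cube& xp, int k, int stride, int Ho, int Wo) {
  const int C = xp.n_slices;
  mat col(Ho * Wo, k * k * C);
  for (int c = 0; c < C; ++c)
    for (int ki = 0; ki < k; ++ki)
      for (int kj = 0; kj < k; ++kj) {
        const int cc = kj + k * ki + k * k * c;
        double* dst = col.colptr(cc);
        if (stride == 1) {
          for (int jo = 0; jo < Wo; ++jo) {
            const double* src = xp.slice_colptr(c, jo + kj) + ki;
            std::memcpy(dst + (size_t)Ho * jo, src, sizeof(double) * Ho);
          }
        } else {
          for (int jo = 0; jo < Wo; ++jo) {
            const double* src = xp.slice_colptr(c, jo * stride + kj) + ki;
            double* d = dst + (size_t)Ho * jo;
            for (int io = 0; io < Ho; ++io) d[io] = src[io * stride];
          }
        }
      }
  return col;
}

static void col2im_add(cube& dxp, const mat& dcol, int k, int stride,
                       int Ho, int Wo) {
  const int C = dxp.n_slices;
  for (int c = 0; c < C; ++c)
    for (int ki = 0; ki < k; ++ki)
      for (int kj = 0; kj < k; ++kj) {
        const int cc = kj + k * ki + k * k * c;
        const double* src = dcol.colptr(cc);
        for (int jo = 0; jo < Wo; ++jo) {
          double* dst = dxp.slice_colptr(c, jo * stride + kj) + ki;
          const double* s = src + (size_t)Ho * jo;
          if (stride == 1)
            for (int io = 0; io < Ho; ++io) dst[io] += s[io];
          else
            for (int io = 0; io < Ho; ++io) dst[io * stride] += s[io];
        }
      }
}

static inline bool use_direct(int stride, int OC) {
  return stride == 1 && OC <= 4;
}

// [[Rcpp::export]]
arma::cube conv2d_forward_cpp(const arma::cube& x, const arma::mat& w,
                              const arma::vec& b, int k, int stride, int pad,
                              int pad_mode) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int OC = w.n_cols;
  cube xp = pad_cube(x, pad, pad_mode);
  cube out(Ho, Wo, OC);
  if (use_direct(stride, OC)) {
    for (int oc = 0; oc < OC; ++oc) out.slice(oc).fill(b[oc]);
    for (int c = 0; c < C; ++c)
      for (int ki = 0; ki < k; ++ki)
        for (int kj = 0; kj < k; ++kj) {
          const int cc = kj + k * ki + k * k * c;
          const auto xs = xp.slice(c).submat(ki, kj, ki + Ho - 1, kj + Wo - 1);
          for (int oc = 0; oc < OC; ++oc)
            out.slice(oc) += w(cc, oc) * xs;
        }
    return out;
  }
  mat col = im2col(xp, k, stride, Ho, Wo);
  mat y = col * w;
  y.each_row() += b.t();
  for (int oc = 0; oc < OC; ++oc)
    out.slice(oc) = reshape(y.col(oc), Ho, Wo);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_backward_cpp(const arma::cube& x, const arma::mat& w,
                               const arma::cube& dy, int k, int stride,
                               int pad, int pad_mode) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = dy.n_rows, Wo = dy.n_cols, OC = dy.n_slices;
  cube xp = pad_cube(x, pad, pad_mode);
  if (use_direct(stride, OC)) {
    mat dW(w.n_rows, w.n_cols, fill::zeros);
    vec db(OC, fill::zeros);
    for (int oc = 0; oc < OC; ++oc) db[oc] = accu(dy.slice(oc));
    cube dxp(xp.n_rows, xp.n_cols, C, fill::zeros);
    for (int c = 0; c < C; ++c)
      for (int ki = 0; ki < k; ++ki)
        for (int kj = 0; kj < k; ++kj) {
          const int cc = kj + k * ki + k * k * c;
          const auto xs = xp.slice(c).submat(ki, kj, ki + Ho - 1, kj + Wo - 1);
          auto dxs = dxp.slice(c).submat(ki, kj, ki + Ho - 1, kj + Wo - 1);
          for (int oc = 0; oc < OC; ++oc) {
            dW(cc, oc) = accu(xs % dy.slice(oc));
            dxs += w(cc, oc) * dy.slice(oc);
          }
        }
    cube dx = unpad_grad(dxp, pad, pad_mode, H, W);
    return Rcpp::List::create(Rcpp::Named("dx") = dx,
                              Rcpp::Named("dw") = dW,
                              Rcpp::Named("db") = db);
  }
  mat col = im2col(xp, k, stride, Ho, Wo);
  mat dY(Ho * Wo, OC);
  for (int oc = 0; oc < OC; ++oc)
    dY.col(oc) = vectorise(dy.slice(oc));
  mat dW = col.t() * dY;
  vec db = sum(dY, 0).t();
  mat dcol = dY * w.t();
  cube dxp(xp.n_rows, xp.n_cols, C, fill::zeros);
  col2im_add(dxp, dcol, k, stride, Ho, Wo);
  cube dx = unpad_grad(dxp, pad, pad_mode, H, W);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dW,
                            Rcpp::Named("db") = db);
}

// ---- batched wrappers ----------------------------------------------------
// Loop over the sample axis of a (H, W, C, N) tensor inside C++, using
// zero-copy views into the R array memory.

// [[Rcpp::export]]
Rcpp::NumericVector conv2d_forward_batch_cpp(Rcpp::NumericVector x4,
                                             const arma::mat& w,
                                             const arma::vec& b, int k,
                                             int stride, int pad,
                                             int pad_mode) {
  Rcpp::IntegerVector d = x4.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int OC = w.n_cols;
  Rcpp::NumericVector y4((size_t)Ho * Wo * OC * N);
  y4.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, OC, N);
  for (int n = 0; n < N; ++n) {
    const cube xn(const_cast<double*>(x4.begin()) + (size_t)n * H * W * C,
                  H, W, C, false, true);
    cube yn = conv2d_forward_cpp(xn, w, b, k, stride, pad, pad_mode);
    std::memcpy(y4.begin() + (size_t)n * Ho * Wo * OC, yn.memptr(),
                sizeof(double) * Ho * Wo * OC);
  }
  return y4;
}

// [[Rcpp::export]]
Rcpp::List conv2d_backward_batch_cpp(Rcpp::NumericVector x4,
                                     const arma::mat& w,
                                     Rcpp::NumericVector dy4, int k,
                                     int stride, int pad, int pad_mode) {
  Rcpp::IntegerVector d = x4.attr("dim");
  Rcpp::IntegerVector dd = dy4.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = dd[0], Wo = dd[1], OC = dd[2];
  Rcpp::NumericVector dx4((size_t)H * W * C * N);
  dx4.attr("dim") = d;
  mat dW(w.n_rows, w.n_cols, fill::zeros);
  vec db(w.n_cols, fill::zeros);
  for (int n = 0; n < N; ++n) {
    const cube xn(const_cast<double*>(x4.begin()) + (size_t)n * H * W * C,
                  H, W, C, false, true);
    const cube dyn(const_cast<double*>(dy4.begin()) + (size_t)n * Ho * Wo * OC,
                   Ho, Wo, OC, false, true);
    Rcpp::List g = conv2d_backward_cpp(xn, w, dyn, k, stride, pad, pad_mode);
    arma::cube dxn = g["dx"];
    std::memcpy(dx4.begin() + (size_t)n * H * W * C, dxn.memptr(),
                sizeof(double) * H * W * C);
    dW += Rcpp::as<arma::mat>(g["dw"]);
    db += Rcpp::as<arma::vec>(g["db"]);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx4,
                            Rcpp::Named("dw") = dW,
                            Rcpp::Named("db") = db);
}
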