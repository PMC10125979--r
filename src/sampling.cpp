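// Trilinear sampling used by grid resampling and line profiles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// coords: N x 3 matrix of 0-based voxel coordinates into `values`
// (axis order matches the array dimensions). Positions outside
// [0, dim-1] on any axis return `outside`.
// [[Rcpp::export]]
Rcpp::NumericVector trilinear_sample_cpp(const arma::cube& values,
                                         const arma::mat& coords,
                                         double outside) {
  const int n1 = values.n_rows, n2 = values.n_cols, n3 = values.n_slices;
  const arma::uword N = coords.n_rows;
  Rcpp::NumericVector out(N);
  for (arma::uword q = 0; q < N; ++q) {
    const double a = coords(q, 0), b = coords(q, 1), c = coords(q, 2);
    if (a < 0 || b < 0 || c < 0 || a > n1 - 1 || b > n2 - 1 || c > n3 - 1) {
      out[q] = outside;
      continue;
    }
    int i0 = (int)std::floor(a), j0 = (int)std::floor(b), k0 = (int)std::floor(c);
    if (i0 == n1 - 1) i0--;
    if (j0 == n2 - 1) j0--;
    if (k0 == n3 - 1) k0--;
    if (n1 == 1) i0 = 0;
    if (n2 == 1) j0 = 0;
    if (n3 == 1) k0 = 0;
    const double fa = a - i0, fb = b - j0, fc = c - k0;
    const int i1 = std::min(i0 + 1, n1 - 1), j1 = std::min(j0 + 1, n2 - 1),
              k1 = std::min(k0 + 1, n3 - 1);
    const double v000 = values(i0, j0, k0), v100 = values(i1, j0, k0),
                 v010 = values(i0, j1, k0), v110 = values(i1, j1, k0),
                 v001 = values(i0, j0, k1), v101 = values(i1, j0, k1),
                 v011 = values(i0, j1, k1), v111 = values(i1, j1, k1);
    const double c00 = v000 * (1 - fa) + v100 * fa;
    const double c10 = v010 * (1 - fa) + v110 * fa;
    const double c01 = v001 * (1 - fa) + v101 * fa;
    const double c11 = v011 * (1 - fa) + v111 * fa;
    const double c0 = c00 * (1 - fb) + c10 * fb;
    const double c1 = c01 * (1 - fb) + c11 * fb;
    out[q] = c0 * (1 - fc) + c1 * fc;
  }
  return out;
}
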