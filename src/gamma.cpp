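// 3D gamma-index kernels. Two routes are compiled on purpose:
//   * gamma_map_cpp   — the shipped kernel: offsets pre-sorted by distance,
//                       early termination once the distance term alone
//                       exceeds the running minimum (exact, just faster);
//   * gamma_map_brute_cpp — plain exhaustive enumeration over the whole
//                       offset set, no early exit, kept as an independent
//                       reference for equivalence testing.
// Both assume co-registered identical grids; voxel (i,j,k) sits at
// (i*s1, j*s2, k*s3) mm. Because reference voxels lie on integer grid
// coordinates, each search offset has fixed fractional interpolation
// weights, precomputed once per offset. Below-threshold reference voxels
// yield NA.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct OffPre {
  int di, dj, dk;          // integer voxel shift
  double fa, fb, fc;       // fractional parts in [0, 1)
  double ov1, ov2, ov3;    // offset in voxel units
  double dist2;            // (|offset| / dta)^2
};

static std::vector<OffPre> precompute_offsets(const mat& offsets,
                                              const vec& spacing,
                                              double dta_mm) {
  const int K = offsets.n_rows;
  std::vector<OffPre> pre(K);
  for (int q = 0; q < K; ++q) {
    OffPre o;
    o.ov1 = offsets(q, 0) / spacing[0];
    o.ov2 = offsets(q, 1) / spacing[1];
    o.ov3 = offsets(q, 2) / spacing[2];
    o.di = (int)std::floor(o.ov1);
    o.dj = (int)std::floor(o.ov2);
    o.dk = (int)std::floor(o.ov3);
    o.fa = o.ov1 - o.di;
    o.fb = o.ov2 - o.dj;
    o.fc = o.ov3 - o.dk;
    o.dist2 = (offsets(q, 0) * offsets(q, 0) + offsets(q, 1) * offsets(q, 1) +
               offsets(q, 2) * offsets(q, 2)) / (dta_mm * dta_mm);
    pre[q] = o;
  }
  return pre;
}

// shared arithmetic: trilinear lerp with per-offset fractions; positions
// outside [0, n-1] on any axis are excluded from the search
static inline bool eval_at(const cube& ev, int i, int j, int k,
                           const OffPre& o, double& de) {
  const int n1 = ev.n_rows, n2 = ev.n_cols, n3 = ev.n_slices;
  const double a = i + o.ov1, b = j + o.ov2, c = k + o.ov3;
  if (a < 0 || b < 0 || c < 0 || a > n1 - 1 || b > n2 - 1 || c > n3 - 1)
    return false;
  const int i0 = i + o.di, j0 = j + o.dj, k0 = k + o.dk;
  const int i1 = std::min(i0 + 1, n1 - 1), j1 = std::min(j0 + 1, n2 - 1),
            k1 = std::min(k0 + 1, n3 - 1);
  const double c00 = ev(i0, j0, k0) * (1 - o.fa) + ev(i1, j0, k0) * o.fa;
  const double c10 = ev(i0, j1, k0) * (1 - o.fa) + ev(i1, j1, k0) * o.fa;
  const double c01 = ev(i0, j0, k1) * (1 - o.fa) + ev(i1, j0, k1) * o.fa;
  const double c11 = ev(i0, j1, k1) * (1 - o.fa) + ev(i1, j1, k1) * o.fa;
  const double d0 = c00 * (1 - o.fb) + c10 * o.fb;
  const double d1 = c01 * (1 - o.fb) + c11 * o.fb;
  de = d0 * (1 - o.fc) + d1 * o.fc;
  return true;
}

// offsets: K x 3 (mm), sorted by ascending Euclidean norm with the zero
// offset first (the early-termination rule relies on the ordering).
// [[Rcpp::export]]
arma::cube gamma_map_cpp(const arma::cube& ref, const arma::cube& ev,
                         const arma::vec& spacing, double dose_crit,
                         double dta_mm, double thresh_abs,
                         const arma::mat& offsets) {
  const int n1 = ref.n_rows, n2 = ref.n_cols, n3 = ref.n_slices;
  std::vector<OffPre> pre = precompute_offsets(offsets, spacing, dta_mm);
  const int K = pre.size();
  cube g(n1, n2, n3);
  g.fill(datum::nan);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        const double dr = ref(i, j, k);
        if (dr < thresh_abs) continue;
        double best = datum::inf;
        for (int q = 0; q < K; ++q) {
          if (pre[q].dist2 >= best) break;  // sorted: nothing better remains
          double de;
          if (!eval_at(ev, i, j, k, pre[q], de)) continue;
          const double dd = (de - dr) / dose_crit;
          const double g2 = dd * dd + pre[q].dist2;
          if (g2 < best) best = g2;
        }
        g(i, j, k) = std::sqrt(best);
      }
  return g;
}

// independent reference: same offset set, full enumeration in the order
// given, no early exit
// [[Rcpp::export]]
arma::cube gamma_map_brute_cpp(const arma::cube& ref, const arma::cube& ev,
                               const arma::vec& spacing, double dose_crit,
                               double dta_mm, double thresh_abs,
                               const arma::mat& offsets) {
  const int n1 = ref.n_rows, n2 = ref.n_cols, n3 = ref.n_slices;
  std::vector<OffPre> pre = precompute_offsets(offsets, spacing, dta_mm);
  const int K = pre.size();
  cube g(n1, n2, n3);
  g.fill(datum::nan);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        const double dr = ref(i, j, k);
        if (dr < thresh_abs) continue;
        double best = datum::inf;
        for (int q = 0; q < K; ++q) {
          double de;
          if (!eval_at(ev, i, j, k, pre[q], de)) continue;
          const double dd = (de - dr) / dose_crit;
          const double g2 = dd * dd + pre[q].dist2;
          if (g2 < best) best = g2;
        }
        g(i, j, k) = std::sqrt(best);
      }
  return g;
}
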