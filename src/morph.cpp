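// Binary morphology for body-mask creation: 3D largest connected component
// (6-connectivity), closing with an ellipsoidal structuring element, and
// slice-wise hole filling. Volumes use axis order (slice, row, column), so
// dimension 1 indexes axial slices.

#include <Rcpp.h>
#include <vector>
#include <queue>

using Rcpp::LogicalVector;
using Rcpp::IntegerVector;

static inline int idx3(int i, int j, int k, int n1, int n2) {
  return i + n1 * (j + (long)n2 * k);
}

// [[Rcpp::export]]
LogicalVector largest_component_cpp(const LogicalVector& mask,
                                    const IntegerVector& dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const long n = (long)n1 * n2 * n3;
  std::vector<int> label(n, 0);
  int best_label = 0;
  long best_size = 0;
  int cur = 0;
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        long p = idx3(i, j, k, n1, n2);
        if (!mask[p] || label[p]) continue;
        ++cur;
        long size = 0;
        std::queue<long> q;
        q.push(p);
        label[p] = cur;
        while (!q.empty()) {
          long v = q.front(); q.pop();
          ++size;
          int vi = v % n1, vj = (v / n1) % n2, vk = v / ((long)n1 * n2);
          for (int d = 0; d < 6; ++d) {
            int ii = vi + di[d], jj = vj + dj[d], kk = vk + dk[d];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
              continue;
            long w = idx3(ii, jj, kk, n1, n2);
            if (mask[w] && !label[w]) { label[w] = cur; q.push(w); }
          }
        }
        if (size > best_size) { best_size = size; best_label = cur; }
      }
  LogicalVector out(n);
  for (long p = 0; p < n; ++p) out[p] = (label[p] == best_label && best_label);
  out.attr("dim") = dims;
  return out;
}

static std::vector<std::array<int, 3>> se_offsets(double r1, double r2, double r3) {
  std::vector<std::array<int, 3>> off;
  int m1 = (int)std::floor(r1), m2 = (int)std::floor(r2), m3 = (int)std::floor(r3);
  for (int k = -m3; k <= m3; ++k)
    for (int j = -m2; j <= m2; ++j)
      for (int i = -m1; i <= m1; ++i) {
        double d = (r1 > 0 ? (double)i * i / (r1 * r1) : (i ? 2.0 : 0.0)) +
                   (r2 > 0 ? (double)j * j / (r2 * r2) : (j ? 2.0 : 0.0)) +
                   (r3 > 0 ? (double)k * k / (r3 * r3) : (k ? 2.0 : 0.0));
        if (d <= 1.0) off.push_back({i, j, k});
      }
  return off;
}

static LogicalVector morph_pass(const LogicalVector& mask,
                                const IntegerVector& dims,
                                const std::vector<std::array<int, 3>>& off,
                                bool dilate) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const long n = (long)n1 * n2 * n3;
  LogicalVector out(n);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        bool hit = !dilate;  // erode: all, dilate: any
        for (size_t d = 0; d < off.size(); ++d) {
          int ii = i + off[d][0], jj = j + off[d][1], kk = k + off[d][2];
          bool v = false;
          if (ii >= 0 && jj >= 0 && kk >= 0 && ii < n1 && jj < n2 && kk < n3)
            v = mask[idx3(ii, jj, kk, n1, n2)];
          if (dilate && v) { hit = true; break; }
          if (!dilate && !v) { hit = false; break; }
        }
        out[idx3(i, j, k, n1, n2)] = hit;
      }
  out.attr("dim") = dims;
  return out;
}

// radii are in voxels per axis (radius 0 disables that axis)
// [[Rcpp::export]]
LogicalVector binary_closing_cpp(const LogicalVector& mask,
                                 const IntegerVector& dims,
                                 double r1, double r2, double r3) {
  std::vector<std::array<int, 3>> off = se_offsets(r1, r2, r3);
  LogicalVector d = morph_pass(mask, dims, off, true);
  return morph_pass(d, dims, off, false);
}

// flood-fill the background of each axial slice (dimension 1 fixed) from the
// slice border; voxels unreachable from the border become foreground
// [[Rcpp::export]]
LogicalVector fill_holes_slices_cpp(const LogicalVector& mask,
                                    const IntegerVector& dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  LogicalVector out(Rcpp::clone(mask));
  std::vector<char> bg((long)n2 * n3);
  for (int s = 0; s < n1; ++s) {
    std::fill(bg.begin(), bg.end(), 0);
    std::queue<std::pair<int, int>> q;
    for (int j = 0; j < n2; ++j)
      for (int k = 0; k < n3; ++k) {
        if (j != 0 && j != n2 - 1 && k != 0 && k != n3 - 1) continue;
        if (!mask[idx3(s, j, k, n1, n2)] && !bg[j + (long)n2 * k]) {
          bg[j + (long)n2 * k] = 1;
          q.push({j, k});
        }
      }
    const int dj[4] = {1, -1, 0, 0}, dk[4] = {0, 0, 1, -1};
    while (!q.empty()) {
      auto v = q.front(); q.pop();
      for (int d = 0; d < 4; ++d) {
        int jj = v.first + dj[d], kk = v.second + dk[d];
        if (jj < 0 || kk < 0 || jj >= n2 || kk >= n3) continue;
        if (!mask[idx3(s, jj, kk, n1, n2)] && !bg[jj + (long)n2 * kk]) {
          bg[jj + (long)n2 * kk] = 1;
          q.push({jj, kk});
        }
      }
    }
    for (int j = 0; j < n2; ++j)
      for (int k = 0; k < n3; ++k)
        if (!bg[j + (long)n2 * k]) out[idx3(s, j, k, n1, n2)] = true;
  }
  out.attr("dim") = dims;
  return out;
}
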