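#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component labeling of a 3D logical array (stack flood fill).
// connectivity: 6 (faces), 18 (faces+edges), 26 (full). A 2D image is the
// z==1 case, where 26-connectivity collapses to 8-connectivity in-plane.
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, int connectivity) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() == 2) {
    IntegerVector d3 = IntegerVector::create(dims[0], dims[1], 1);
    dims = d3;
  }
  if (dims.size() != 3) stop("mask must be a 2D or 3D array");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbor offsets
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nnz = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nnz == 0) continue;
        if (connectivity == 6 && nnz > 1) continue;
        if (connectivity == 18 && nnz > 2) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }

  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = IntegerVector::create(nx, ny, nz);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int cz = (int)(cur / ((R_xlen_t)nx * ny));
      int rem = (int)(cur % ((R_xlen_t)nx * ny));
      int cy = rem / nx, cx = rem % nx;
      for (size_t k = 0; k < ox.size(); ++k) {
        int x = cx + ox[k], y = cy + oy[k], z = cz + oz[k];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        R_xlen_t j = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}

// Exact multilevel Otsu via dynamic programming on the histogram of the
// distinct intensities present. Maximizes the between-class variance
// sum_c w_c * mu_c^2 (equivalent up to a constant) over k ascending cut
// points; classes are the intervals (t_{c-1}, t_c]. Returns 1-based indices
// into `values` of the k chosen thresholds.
// [[Rcpp::export(name = ".multiotsu_dp")]]
IntegerVector multiotsu_dp(NumericVector counts, NumericVector values, int k) {
  const int d = counts.size();
  if (values.size() != d) stop("counts/values length mismatch");
  if (k < 1) stop("k must be >= 1");
  if (d < k + 1) stop("need at least k+1 distinct intensities");
  std::vector<double> W(d + 1, 0.0), S(d + 1, 0.0);
  for (int i = 0; i < d; ++i) {
    W[i + 1] = W[i] + counts[i];
    S[i + 1] = S[i] + counts[i] * values[i];
  }
  auto g = [&](int a, int b) {        // class score over bins a..b inclusive
    double w = W[b + 1] - W[a];
    if (w <= 0) return 0.0;
    double s = S[b + 1] - S[a];
    return s * s / w;
  };
  // f[c][j]: best score, bins 0..j split into c+1 classes; cut[c][j] last cut
  std::vector< std::vector<double> > f(k + 1, std::vector<double>(d, 0.0));
  std::vector< std::vector<int> > cut(k + 1, std::vector<int>(d, -1));
  for (int j = 0; j < d; ++j) f[0][j] = g(0, j);
  for (int c = 1; c <= k; ++c) {
    for (int j = c; j < d; ++j) {
      double best = -1.0; int arg = -1;
      for (int i = c - 1; i < j; ++i) {
        double val = f[c - 1][i] + g(i + 1, j);
        if (val > best) { best = val; arg = i; }
      }
      f[c][j] = best; cut[c][j] = arg;
    }
  }
  IntegerVector th(k);
  int j = d - 1;
  for (int c = k; c >= 1; --c) {
    int i = cut[c][j];
    th[c - 1] = i + 1;  // 1-based index of the bin ending class c
    j = i;
  }
  return th;
}

// For each row of `a`, the minimum Euclidean distance to any row of `b`.
// Columns are coordinates already scaled to physical units.
// [[Rcpp::export(name = ".nn_min_dist")]]
NumericVector nn_min_dist(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow(), nc = a.ncol();
  if (b.ncol() != nc) stop("dimension mismatch");
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int c = 0; c < nc; ++c) {
        double dd = a(i, c) - b(j, c);
        s += dd * dd;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
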