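#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// 3D binary morphology primitives. Volumes are flat vectors in R
// column-major order, dim = (n1, n2, n3), first index fastest.

namespace {

struct Offsets {
  std::vector<int> d1, d2, d3;
};

// Neighborhood offsets for 6 (face), 18 (face+edge) or 26 (full) connectivity.
Offsets make_offsets(int connectivity) {
  Offsets o;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int nz = std::abs(a) + std::abs(b) + std::abs(c);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        o.d1.push_back(a); o.d2.push_back(b); o.d3.push_back(c);
      }
  return o;
}

} // namespace

// Connected-component labeling of a binary volume. Returns integer labels
// in discovery (raster scan) order, 0 for background.
// [[Rcpp::export]]
IntegerVector label_components_cpp(const IntegerVector& mask,
                                   const IntegerVector& dim,
                                   int connectivity) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  Offsets off = make_offsets(connectivity);
  const int K = off.d1.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || labels[s] != 0) continue;
    ++cur;
    labels[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int i1 = (int)(v % n1);
      int i2 = (int)((v / n1) % n2);
      int i3 = (int)(v / ((R_xlen_t)n1 * n2));
      for (int k = 0; k < K; ++k) {
        int j1 = i1 + off.d1[k], j2 = i2 + off.d2[k], j3 = i3 + off.d3[k];
        if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3)
          continue;
        R_xlen_t w = j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3);
        if (mask[w] != 0 && labels[w] == 0) {
          labels[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}

namespace {

// 1D squared distance transform (lower envelope of parabolas).
void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
          std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DBL_MAX;
  z[1] = DBL_MAX;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DBL_MAX;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

void dt_axis(std::vector<double>& g, int n1, int n2, int n3, int axis) {
  int nax = (axis == 1) ? n1 : (axis == 2 ? n2 : n3);
  R_xlen_t stride = (axis == 1) ? 1 : (axis == 2 ? (R_xlen_t)n1
                                                 : (R_xlen_t)n1 * n2);
  std::vector<double> f(nax), d(nax), z(nax + 1);
  std::vector<int> v(nax);
  int m2 = (axis == 1) ? n2 : n1;
  int m3 = (axis == 3) ? n2 : n3;
  R_xlen_t s2 = (axis == 1) ? (R_xlen_t)n1 : 1;
  R_xlen_t s3 = (axis == 3) ? (R_xlen_t)n1 : (R_xlen_t)n1 * n2;
  for (int i3 = 0; i3 < m3; ++i3) {
    for (int i2 = 0; i2 < m2; ++i2) {
      R_xlen_t base = i2 * s2 + i3 * s3;
      for (int q = 0; q < nax; ++q) f[q] = g[base + q * stride];
      dt1d(f, d, nax, v, z);
      for (int q = 0; q < nax; ++q) g[base + q * stride] = d[q];
    }
  }
}

} // namespace

// Exact Euclidean distance transform of a binary volume: for each
// foreground voxel, the distance to the nearest background voxel
// (volume faces are not treated as background).
// [[Rcpp::export]]
NumericVector edt3d_cpp(const IntegerVector& mask, const IntegerVector& dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> g(n);
  const double INF = 1e20;
  bool any_bg = false;
  for (R_xlen_t i = 0; i < n; ++i) {
    g[i] = (mask[i] != 0) ? INF : 0.0;
    if (mask[i] == 0) any_bg = true;
  }
  if (any_bg) {
    dt_axis(g, n1, n2, n3, 1);
    dt_axis(g, n1, n2, n3, 2);
    dt_axis(g, n1, n2, n3, 3);
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = any_bg ? std::sqrt(g[i]) : INF;
  return out;
}

namespace {

struct QNode {
  double h;        // height (distance-map value); larger floods first
  R_xlen_t order;  // FIFO tie-break for determinism
  R_xlen_t idx;
  int label;
};

struct QCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.h != b.h) return a.h < b.h;   // max-heap on height
    return a.order > b.order;           // then first-in first-out
  }
};

} // namespace

// Marker-based watershed on a height map (typically the EDT), flooding
// downhill from seeds, restricted to voxels of the same pre-computed
// connected component so watershed can only refine, never merge,
// components. seeds are 1-based linear indices.
// [[Rcpp::export]]
IntegerVector watershed_flood_cpp(const NumericVector& height,
                                  const IntegerVector& comp,
                                  const IntegerVector& seeds,
                                  const IntegerVector& dim,
                                  int connectivity) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  Offsets off = make_offsets(connectivity);
  const int K = off.d1.size();

  IntegerVector labels(n, 0);
  std::priority_queue<QNode, std::vector<QNode>, QCmp> pq;
  R_xlen_t order = 0;

  for (int s = 0; s < seeds.size(); ++s) {
    R_xlen_t idx = (R_xlen_t)seeds[s] - 1;
    pq.push(QNode{height[idx], order++, idx, s + 1});
  }

  while (!pq.empty()) {
    QNode nd = pq.top(); pq.pop();
    if (labels[nd.idx] != 0) continue;
    labels[nd.idx] = nd.label;
    int i1 = (int)(nd.idx % n1);
    int i2 = (int)((nd.idx / n1) % n2);
    int i3 = (int)(nd.idx / ((R_xlen_t)n1 * n2));
    for (int k = 0; k < K; ++k) {
      int j1 = i1 + off.d1[k], j2 = i2 + off.d2[k], j3 = i3 + off.d3[k];
      if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3)
        continue;
      R_xlen_t w = j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3);
      if (labels[w] == 0 && comp[w] != 0 && comp[w] == comp[nd.idx])
        pq.push(QNode{height[w], order++, w, nd.label});
    }
  }
  return labels;
}
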