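#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

// Volumes are passed as flat vectors in R column-major order with dim
// (n1, n2, n3), first index fastest. Axis is 1-based.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline int reflecti(int v, int n) {
  // reflect-without-repeat (mirror about the edge voxel centers)
  if (n == 1) return 0;
  int period = 2 * (n - 1);
  v = ((v % period) + period) % period;
  return v < n ? v : period - v;
}

// Correlation of a complex volume with a short complex kernel along one
// axis: out[i] = sum_j k[j] * x[i + (j - center) * stride], the off-axis
// coordinates held fixed. Out-of-range samples are clamped to the edge;
// callers exclude the margin so clamped values never reach a feature.
// [[Rcpp::export]]
ComplexVector conv_axis_cplx(const ComplexVector& x, const IntegerVector& dim,
                             const ComplexVector& kernel, int axis, int center) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int L = kernel.size();
  const std::complex<double>* xc =
    reinterpret_cast<const std::complex<double>*>(&x[0]);
  std::vector<std::complex<double>> k(L);
  for (int j = 0; j < L; ++j)
    k[j] = std::complex<double>(kernel[j].r, kernel[j].i);

  ComplexVector out(x.size());
  std::complex<double>* oc = reinterpret_cast<std::complex<double>*>(&out[0]);

  const int nax = (axis == 1) ? n1 : (axis == 2 ? n2 : n3);
  const R_xlen_t stride = (axis == 1) ? 1 : (axis == 2 ? (R_xlen_t)n1
                                                       : (R_xlen_t)n1 * n2);
  for (int i3 = 0; i3 < n3; ++i3) {
    for (int i2 = 0; i2 < n2; ++i2) {
      R_xlen_t base = (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3);
      for (int i1 = 0; i1 < n1; ++i1) {
        R_xlen_t idx = base + i1;
        int pos = (axis == 1) ? i1 : (axis == 2 ? i2 : i3);
        R_xlen_t off = idx - (R_xlen_t)pos * stride;
        std::complex<double> acc(0.0, 0.0);
        for (int j = 0; j < L; ++j) {
          int p = clampi(pos + j - center, 0, nax - 1);
          acc += k[j] * xc[off + (R_xlen_t)p * stride];
        }
        oc[idx] = acc;
      }
    }
  }
  return out;
}

// Real 1D correlation along an axis with reflect boundary handling;
// used for separable Gaussian smoothing.
// [[Rcpp::export]]
NumericVector conv_axis_real(const NumericVector& x, const IntegerVector& dim,
                             const NumericVector& kernel, int axis, int center) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int L = kernel.size();
  NumericVector out(x.size());
  const int nax = (axis == 1) ? n1 : (axis == 2 ? n2 : n3);
  const R_xlen_t stride = (axis == 1) ? 1 : (axis == 2 ? (R_xlen_t)n1
                                                       : (R_xlen_t)n1 * n2);
  for (int i3 = 0; i3 < n3; ++i3) {
    for (int i2 = 0; i2 < n2; ++i2) {
      R_xlen_t base = (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3);
      for (int i1 = 0; i1 < n1; ++i1) {
        R_xlen_t idx = base + i1;
        int pos = (axis == 1) ? i1 : (axis == 2 ? i2 : i3);
        R_xlen_t off = idx - (R_xlen_t)pos * stride;
        double acc = 0.0;
        for (int j = 0; j < L; ++j) {
          int p = reflecti(pos + j - center, nax);
          acc += kernel[j] * x[off + (R_xlen_t)p * stride];
        }
        out[idx] = acc;
      }
    }
  }
  return out;
}
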