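#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// round half away from zero (nearest-neighbour tie-break)
static inline int round_half_away(double x) {
  return (x >= 0.0) ? (int)std::floor(x + 0.5) : (int)std::ceil(x - 0.5);
}

// Sample a 2D/3D array at continuous 0-based index coordinates.
// Out-of-domain samples (any corner outside the lattice for linear, rounded
// index outside for nearest) contribute `background`.
// [[Rcpp::export]]
NumericVector cpp_interp(NumericVector values, NumericMatrix idx,
                         bool nearest, double background) {
  IntegerVector dim = values.attr("dim");
  const int d = dim.size();
  if (d != 2 && d != 3)
    stop("cpp_interp: only 2D and 3D arrays supported");
  if (idx.ncol() != d)
    stop("cpp_interp: coordinate dimensionality mismatch");
  const int n0 = dim[0];
  const int n1 = dim[1];
  const int n2 = (d == 3) ? dim[2] : 1;
  const R_xlen_t np = idx.nrow();
  NumericVector out(np);
  const double* v = values.begin();

  if (nearest) {
    for (R_xlen_t p = 0; p < np; ++p) {
      int i = round_half_away(idx(p, 0));
      int j = round_half_away(idx(p, 1));
      int k = (d == 3) ? round_half_away(idx(p, 2)) : 0;
      if (i < 0 || i >= n0 || j < 0 || j >= n1 || k < 0 || k >= n2) {
        out[p] = background;
      } else {
        out[p] = v[(R_xlen_t)i + (R_xlen_t)n0 * (j + (R_xlen_t)n1 * k)];
      }
    }
    return out;
  }

  for (R_xlen_t p = 0; p < np; ++p) {
    double x = idx(p, 0), y = idx(p, 1), z = (d == 3) ? idx(p, 2) : 0.0;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
        k0 = (int)std::floor(z);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double acc = 0.0;
    int kmax = (d == 3) ? 1 : 0;
    for (int dk = 0; dk <= kmax; ++dk) {
      double wz = (d == 3) ? (dk ? fz : 1.0 - fz) : 1.0;
      if (wz == 0.0) continue;
      int k = k0 + dk;
      for (int dj = 0; dj <= 1; ++dj) {
        double wy = dj ? fy : 1.0 - fy;
        if (wy == 0.0) continue;
        int j = j0 + dj;
        for (int di = 0; di <= 1; ++di) {
          double wx = di ? fx : 1.0 - fx;
          if (wx == 0.0) continue;
          int i = i0 + di;
          double val;
          if (i < 0 || i >= n0 || j < 0 || j >= n1 || k < 0 || k >= n2)
            val = background;
          else
            val = v[(R_xlen_t)i + (R_xlen_t)n0 * (j + (R_xlen_t)n1 * k)];
          acc += wx * wy * wz * val;
        }
      }
    }
    out[p] = acc;
  }
  return out;
}

// Separable Gaussian smoothing of a d-dimensional array, sigma per axis in
// voxel units. Kernel truncated at 3 sigma and renormalised over in-range
// taps, so constants are preserved up to the boundary.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector values, NumericVector sigmas) {
  IntegerVector dim = values.attr("dim");
  const int d = dim.size();
  if ((int)sigmas.size() != d)
    stop("cpp_gauss_smooth: need one sigma per axis");
  R_xlen_t total = 1;
  for (int a = 0; a < d; ++a) total *= dim[a];
  NumericVector cur = clone(values);
  NumericVector buf(total);

  for (int a = 0; a < d; ++a) {
    double sigma = sigmas[a];
    if (sigma <= 0.0) continue;
    int radius = (int)std::ceil(3.0 * sigma);
    if (radius < 1) radius = 1;
    std::vector<double> w(2 * radius + 1);
    for (int t = -radius; t <= radius; ++t)
      w[t + radius] = std::exp(-0.5 * (t / sigma) * (t / sigma));

    R_xlen_t stride = 1;
    for (int b = 0; b < a; ++b) stride *= dim[b];
    const int len = dim[a];
    const R_xlen_t nouter = total / (stride * len);
    const double* src = cur.begin();
    double* dst = buf.begin();

    for (R_xlen_t outer = 0; outer < nouter; ++outer) {
      const R_xlen_t base = outer * stride * len;
      for (R_xlen_t inner = 0; inner < stride; ++inner) {
        for (int i = 0; i < len; ++i) {
          double acc = 0.0, wsum = 0.0;
          int tlo = std::max(-radius, -i);
          int thi = std::min(radius, len - 1 - i);
          for (int t = tlo; t <= thi; ++t) {
            double ww = w[t + radius];
            acc += ww * src[base + inner + (R_xlen_t)(i + t) * stride];
            wsum += ww;
          }
          dst[base + inner + (R_xlen_t)i * stride] = acc / wsum;
        }
      }
    }
    std::swap(cur, buf);
  }
  cur.attr("dim") = dim;
  return cur;
}
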