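// Kaiser-Bessel gridding primitives for 3D non-Cartesian k-space.
//
// Conventions: sample coordinates u are in oversampled-grid units, centered
// (u = k[cycles/mm] * G * voxel_size), valid range [-G/2, G/2). The grid is
// stored with axis index ix representing centered coordinate ix - G/2, and
// out-of-range kernel taps wrap periodically (standard gridding practice;
// the oversampling guard band keeps aliased energy negligible).

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double kb_kernel(double t, double halfw, double beta) {
  // unnormalized Kaiser-Bessel: I0(beta * sqrt(1 - (t/halfw)^2)) on |t|<=halfw
  double r = t / halfw;
  double s = 1.0 - r * r;
  if (s <= 0.0) return 0.0;
  return R::bessel_i(beta * std::sqrt(s), 0.0, 1.0);
}

struct AxisTaps {
  int idx[8];      // wrapped grid indices
  double w[8];     // kernel weights
  int n;
};

static inline void axis_taps(double u, int G, int W, double beta, AxisTaps &t) {
  double halfw = 0.5 * W;
  int lo = (int)std::ceil(u - halfw);
  int hi = (int)std::floor(u + halfw);
  t.n = 0;
  for (int j = lo; j <= hi && t.n < 8; ++j) {
    double kw = kb_kernel((double)j - u, halfw, beta);
    if (kw == 0.0) continue;
    int gi = (j + G / 2) % G;
    if (gi < 0) gi += G;
    t.idx[t.n] = gi;
    t.w[t.n] = kw;
    ++t.n;
  }
}

// [[Rcpp::export(name = ".kb_spread3")]]
ComplexVector kb_spread3(NumericMatrix u, ComplexVector vals, int G, int W,
                         double beta) {
  int n = u.nrow();
  if (vals.size() != n) stop("coordinate/value length mismatch");
  std::vector<std::complex<double> > grid((size_t)G * G * G,
                                          std::complex<double>(0.0, 0.0));
  AxisTaps tx, ty, tz;
  for (int i = 0; i < n; ++i) {
    axis_taps(u(i, 0), G, W, beta, tx);
    axis_taps(u(i, 1), G, W, beta, ty);
    axis_taps(u(i, 2), G, W, beta, tz);
    std::complex<double> v(vals[i].r, vals[i].i);
    for (int c = 0; c < tz.n; ++c) {
      size_t oz = (size_t)tz.idx[c] * G * G;
      std::complex<double> vz = v * tz.w[c];
      for (int b = 0; b < ty.n; ++b) {
        size_t oy = oz + (size_t)ty.idx[b] * G;
        std::complex<double> vy = vz * ty.w[b];
        for (int a = 0; a < tx.n; ++a) {
          grid[oy + tx.idx[a]] += vy * tx.w[a];
        }
      }
    }
  }
  ComplexVector out((size_t)G * G * G);
  for (size_t i = 0; i < grid.size(); ++i) {
    out[i].r = grid[i].real();
    out[i].i = grid[i].imag();
  }
  return out;
}

// [[Rcpp::export(name = ".kb_interp3")]]
ComplexVector kb_interp3(ComplexVector grid, NumericMatrix u, int G, int W,
                         double beta) {
  if ((size_t)grid.size() != (size_t)G * G * G) stop("grid size mismatch");
  int n = u.nrow();
  ComplexVector out(n);
  AxisTaps tx, ty, tz;
  for (int i = 0; i < n; ++i) {
    axis_taps(u(i, 0), G, W, beta, tx);
    axis_taps(u(i, 1), G, W, beta, ty);
    axis_taps(u(i, 2), G, W, beta, tz);
    std::complex<double> acc(0.0, 0.0);
    for (int c = 0; c < tz.n; ++c) {
      size_t oz = (size_t)tz.idx[c] * G * G;
      for (int b = 0; b < ty.n; ++b) {
        size_t oy = oz + (size_t)ty.idx[b] * G;
        double wyz = tz.w[c] * ty.w[b];
        for (int a = 0; a < tx.n; ++a) {
          Rcomplex g = grid[oy + tx.idx[a]];
          double w = wyz * tx.w[a];
          acc += std::complex<double>(g.r * w, g.i * w);
        }
      }
    }
    out[i].r = acc.real();
    out[i].i = acc.imag();
  }
  return out;
}
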