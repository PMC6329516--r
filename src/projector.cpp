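#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Joseph-style (driving-axis, bilinear-slice interpolation) ray tracing for an
// infinitely narrow beam.  forward (gather) and back (scatter) share the same
// interpolation weights so back_project is the exact numerical transpose of
// forward_project.
//
// Conventions: voxel (i,j,k) is 0-based, its center sits at
//   low[a] + i * sp[a]   (low = center of voxel 0 along axis a, mm)
// volume is column-major with dims n[0] x n[1] x n[2];
// sinogram is column-major nViews x nRows x nChannels.

namespace {

struct Grid {
  const int *n;
  const double *sp;
  double low[3];
};

// clamp the slice range [k0, k1] so that f(k) = f0 + k*df stays in [lo, hi]
inline void clampRange(double f0, double df, double lo, double hi, int &k0,
                       int &k1) {
  if (df > 1e-300) {
    k0 = std::max(k0, (int)std::ceil((lo - f0) / df));
    k1 = std::min(k1, (int)std::floor((hi - f0) / df));
  } else if (df < -1e-300) {
    k0 = std::max(k0, (int)std::ceil((hi - f0) / df));
    k1 = std::min(k1, (int)std::floor((lo - f0) / df));
  } else if (f0 < lo || f0 > hi) {
    k1 = k0 - 1; // empty
  }
}

// One ray from S to P. gather: returns line integral of vol.
// scatter: adds sval * weight pattern into vol.  Fractional in-slice
// coordinates advance linearly with the slice index, so the inner loop is
// incremental.
template <bool Gather>
double traceRay(const Grid &g, const double S[3], const double P[3],
                const double *volIn, double *volOut, double sval) {
  double dir[3];
  double len = 0.0;
  for (int a = 0; a < 3; ++a) {
    dir[a] = P[a] - S[a];
    len += dir[a] * dir[a];
  }
  len = std::sqrt(len);
  if (len <= 0.0) return 0.0;
  for (int a = 0; a < 3; ++a) dir[a] /= len;

  // driving axis: largest |direction| component
  int d = 0;
  if (std::fabs(dir[1]) > std::fabs(dir[d])) d = 1;
  if (std::fabs(dir[2]) > std::fabs(dir[d])) d = 2;
  const int a1 = (d + 1) % 3, a2 = (d + 2) % 3;

  const double step = g.sp[d] / std::fabs(dir[d]);
  const int nd = g.n[d], n1 = g.n[a1], n2 = g.n[a2];

  // strides in the column-major volume
  const long stride[3] = {1, (long)g.n[0], (long)g.n[0] * g.n[1]};
  const long s1 = stride[a1], s2 = stride[a2], sd = stride[d];

  // fractional indices on slice k: f(k) = f0 + k * df
  const double invd = 1.0 / dir[d];
  const double t0 = (g.low[d] - S[d]) * invd;
  const double dt = g.sp[d] * invd;
  const double f10 = (S[a1] + t0 * dir[a1] - g.low[a1]) / g.sp[a1];
  const double df1 = dt * dir[a1] / g.sp[a1];
  const double f20 = (S[a2] + t0 * dir[a2] - g.low[a2]) / g.sp[a2];
  const double df2 = dt * dir[a2] / g.sp[a2];

  int k0 = 0, k1 = nd - 1;
  clampRange(f10, df1, -1.0 + 1e-12, n1 - 1e-12, k0, k1);
  clampRange(f20, df2, -1.0 + 1e-12, n2 - 1e-12, k0, k1);
  if (k1 < k0) return 0.0;

  double f1 = f10 + k0 * df1;
  double f2 = f20 + k0 * df2;
  double acc = 0.0;
  for (int k = k0; k <= k1; ++k, f1 += df1, f2 += df2) {
    const int i1 = (int)std::floor(f1);
    const int i2 = (int)std::floor(f2);
    const double w1 = f1 - i1, w2 = f2 - i2;
    const long base = (long)k * sd + (long)i1 * s1 + (long)i2 * s2;
    const bool ok1l = i1 >= 0, ok1h = i1 < n1 - 1;
    const bool ok2l = i2 >= 0, ok2h = i2 < n2 - 1;
    if (ok1l & ok1h & ok2l & ok2h) { // fast interior path
      if (Gather) {
        acc += (1 - w1) * ((1 - w2) * volIn[base] + w2 * volIn[base + s2]) +
               w1 * ((1 - w2) * volIn[base + s1] + w2 * volIn[base + s1 + s2]);
      } else {
        const double v = step * sval;
        volOut[base] += (1 - w1) * (1 - w2) * v;
        volOut[base + s1] += w1 * (1 - w2) * v;
        volOut[base + s2] += (1 - w1) * w2 * v;
        volOut[base + s1 + s2] += w1 * w2 * v;
      }
    } else { // boundary: guard each neighbor
      if (ok1l && ok2l) {
        if (Gather) acc += (1 - w1) * (1 - w2) * volIn[base];
        else volOut[base] += (1 - w1) * (1 - w2) * step * sval;
      }
      if (ok1h && ok2l) {
        if (Gather) acc += w1 * (1 - w2) * volIn[base + s1];
        else volOut[base + s1] += w1 * (1 - w2) * step * sval;
      }
      if (ok1l && ok2h) {
        if (Gather) acc += (1 - w1) * w2 * volIn[base + s2];
        else volOut[base + s2] += (1 - w1) * w2 * step * sval;
      }
      if (ok1h && ok2h) {
        if (Gather) acc += w1 * w2 * volIn[base + s1 + s2];
        else volOut[base + s1 + s2] += w1 * w2 * step * sval;
      }
    }
  }
  return Gather ? acc * step : 0.0;
}

inline void cellCenter(const double *detC, const double *eu, const double *ev,
                       double uoff, double voff, double out[3]) {
  for (int a = 0; a < 3; ++a) out[a] = detC[a] + uoff * eu[a] + voff * ev[a];
}

} // namespace

// [[Rcpp::export(name = ".cppForwardProject")]]
NumericVector cppForwardProject(NumericVector vol, IntegerVector dims,
                                NumericVector spacing, NumericVector lowCorner,
                                NumericMatrix src, NumericMatrix detC,
                                NumericMatrix eu, NumericMatrix ev,
                                int nRows, int nChannels, double rowHeight,
                                double channelWidth) {
  const int nViews = src.nrow();
  Grid g;
  g.n = INTEGER(dims);
  g.sp = REAL(spacing);
  for (int a = 0; a < 3; ++a) g.low[a] = lowCorner[a];

  NumericVector sino((R_xlen_t)nViews * nRows * nChannels);
  const double *pv = REAL(vol);
  double *ps = REAL(sino);

  for (int v = 0; v < nViews; ++v) {
    double S[3], C[3], U[3], V[3];
    for (int a = 0; a < 3; ++a) {
      S[a] = src(v, a);
      C[a] = detC(v, a);
      U[a] = eu(v, a);
      V[a] = ev(v, a);
    }
    for (int c = 0; c < nChannels; ++c) {
      const double uoff = (c - 0.5 * (nChannels - 1)) * channelWidth;
      for (int r = 0; r < nRows; ++r) {
        const double voff = (r - 0.5 * (nRows - 1)) * rowHeight;
        double P[3];
        cellCenter(C, U, V, uoff, voff, P);
        ps[(R_xlen_t)v + (R_xlen_t)nViews * (r + (R_xlen_t)nRows * c)] =
            traceRay<true>(g, S, P, pv, nullptr, 0.0);
      }
    }
  }
  sino.attr("dim") = IntegerVector::create(nViews, nRows, nChannels);
  return sino;
}

// [[Rcpp::export(name = ".cppBackProject")]]
NumericVector cppBackProject(NumericVector sino, IntegerVector dims,
                             NumericVector spacing, NumericVector lowCorner,
                             NumericMatrix src, NumericMatrix detC,
                             NumericMatrix eu, NumericMatrix ev, int nRows,
                             int nChannels, double rowHeight,
                             double channelWidth) {
  const int nViews = src.nrow();
  Grid g;
  g.n = INTEGER(dims);
  g.sp = REAL(spacing);
  for (int a = 0; a < 3; ++a) g.low[a] = lowCorner[a];

  NumericVector vol((R_xlen_t)dims[0] * dims[1] * dims[2]);
  double *pv = REAL(vol);
  const double *ps = REAL(sino);

  for (int v = 0; v < nViews; ++v) {
    double S[3], C[3], U[3], V[3];
    for (int a = 0; a < 3; ++a) {
      S[a] = src(v, a);
      C[a] = detC(v, a);
      U[a] = eu(v, a);
      V[a] = ev(v, a);
    }
    for (int c = 0; c < nChannels; ++c) {
      const double uoff = (c - 0.5 * (nChannels - 1)) * channelWidth;
      for (int r = 0; r < nRows; ++r) {
        const double voff = (r - 0.5 * (nRows - 1)) * rowHeight;
        const double sval =
            ps[(R_xlen_t)v + (R_xlen_t)nViews * (r + (R_xlen_t)nRows * c)];
        if (sval == 0.0) continue;
        double P[3];
        cellCenter(C, U, V, uoff, voff, P);
        traceRay<false>(g, S, P, nullptr, pv, sval);
      }
    }
  }
  vol.attr("dim") = dims;
  return vol;
}

// Voxel-driven weighted backprojection for the simplified helical FDK.
// qf holds the cosine-weighted, ramp-filtered projections on the virtual
// detector through the isocenter (spacings chIso/rowIso, mm).  For every voxel
// the views whose detector window covers it contribute (R/l)^2 times the
// bilinearly interpolated filtered value; coverage counts are returned for the
// per-voxel angular redundancy normalization done in R.
// [[Rcpp::export(name = ".cppFdkBackProject")]]
List cppFdkBackProject(NumericVector qf, IntegerVector dims,
                       NumericVector spacing, NumericVector lowCorner,
                       NumericMatrix src, NumericMatrix ehat, NumericMatrix eu,
                       NumericMatrix ev, int nRows, int nChannels,
                       double rowIso, double chIso, double sourceRadius) {
  const int nViews = src.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector vol((R_xlen_t)nx * ny * nz);
  IntegerVector cnt((R_xlen_t)nx * ny * nz);
  double *pv = REAL(vol);
  int *pc = INTEGER(cnt);
  const double *pq = REAL(qf);
  const double R2 = sourceRadius * sourceRadius;

  for (int v = 0; v < nViews; ++v) {
    double S[3], H[3], U[3], V[3];
    for (int a = 0; a < 3; ++a) {
      S[a] = src(v, a);
      H[a] = ehat(v, a); // unit vector source -> isocenter (central ray)
      U[a] = eu(v, a);
      V[a] = ev(v, a);
    }
    long idx = 0;
    for (int k = 0; k < nz; ++k) {
      const double qz = lowCorner[2] + k * spacing[2];
      for (int j = 0; j < ny; ++j) {
        const double qy = lowCorner[1] + j * spacing[1];
        for (int i = 0; i < nx; ++i, ++idx) {
          const double qx = lowCorner[0] + i * spacing[0];
          const double wx = qx - S[0], wy = qy - S[1], wz = qz - S[2];
          const double l = wx * H[0] + wy * H[1] + wz * H[2];
          if (l <= 0.0) continue;
          const double mag = sourceRadius / l;
          const double uIso = mag * (wx * U[0] + wy * U[1] + wz * U[2]);
          const double vIso = mag * (wx * V[0] + wy * V[1] + wz * V[2]);
          const double ci = uIso / chIso + 0.5 * (nChannels - 1);
          const double ri = vIso / rowIso + 0.5 * (nRows - 1);
          if (ci < 0.0 || ci > nChannels - 1 || ri < 0.0 || ri > nRows - 1)
            continue;
          const int c0 = (int)std::floor(std::min(ci, nChannels - 1.000001));
          const int r0 = (int)std::floor(std::min(ri, nRows - 1.000001));
          const double fc = ci - c0, fr = ri - r0;
          const R_xlen_t b00 =
              (R_xlen_t)v + (R_xlen_t)nViews * (r0 + (R_xlen_t)nRows * c0);
          const R_xlen_t b10 = b00 + (R_xlen_t)nViews; // next row
          const R_xlen_t b01 = b00 + (R_xlen_t)nViews * nRows; // next channel
          const R_xlen_t b11 = b01 + (R_xlen_t)nViews;
          const double val = (1 - fr) * (1 - fc) * pq[b00] +
                             fr * (1 - fc) * pq[b10] +
                             (1 - fr) * fc * pq[b01] + fr * fc * pq[b11];
          pv[idx] += (R2 / (l * l)) * val;
          pc[idx] += 1;
        }
      }
    }
  }
  vol.attr("dim") = dims;
  cnt.attr("dim") = dims;
  return List::create(_["sum"] = vol, _["count"] = cnt);
}
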