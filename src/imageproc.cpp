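// Resampling and exact Euclidean distance transform.
//
// Volumes here are plain 3D arrays dim (n1, n2, n3) with a physical spacing
// per axis; the physical coordinate of voxel index i (0-based) along an axis
// is i * spacing. Resampling maps output index j to input index
// j * sp_out / sp_in (shared grid origin), trilinear for images and
// round-to-nearest for masks.

#include <Rcpp.h>
using namespace Rcpp;

static inline double at(const double* v, int n1, int n2, int i1, int i2, int i3) {
  return v[i1 + (std::size_t)n1 * (i2 + (std::size_t)n2 * i3)];
}

// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector vol, NumericVector sp_in,
                             NumericVector sp_out, IntegerVector out_dim,
                             bool nearest) {
  IntegerVector d = vol.attr("dim");
  const int n1 = d[0], n2 = d[1], n3 = d[2];
  const int m1 = out_dim[0], m2 = out_dim[1], m3 = out_dim[2];
  const double r1 = sp_out[0] / sp_in[0], r2 = sp_out[1] / sp_in[1],
               r3 = sp_out[2] / sp_in[2];
  NumericVector out((std::size_t)m1 * m2 * m3);
  out.attr("dim") = out_dim;
  const double* v = vol.begin();
  double* o = out.begin();
  for (int j3 = 0; j3 < m3; ++j3) {
    const double x3 = j3 * r3;
    for (int j2 = 0; j2 < m2; ++j2) {
      const double x2 = j2 * r2;
      for (int j1 = 0; j1 < m1; ++j1) {
        const double x1 = j1 * r1;
        double val;
        if (nearest) {
          int i1 = (int)std::lround(x1), i2 = (int)std::lround(x2),
              i3 = (int)std::lround(x3);
          i1 = std::min(std::max(i1, 0), n1 - 1);
          i2 = std::min(std::max(i2, 0), n2 - 1);
          i3 = std::min(std::max(i3, 0), n3 - 1);
          val = at(v, n1, n2, i1, i2, i3);
        } else {
          int f1 = (int)std::floor(x1), f2 = (int)std::floor(x2),
              f3 = (int)std::floor(x3);
          double t1 = x1 - f1, t2 = x2 - f2, t3 = x3 - f3;
          // clamp so border voxels extrapolate flat
          if (f1 < 0) { f1 = 0; t1 = 0.0; }
          if (f2 < 0) { f2 = 0; t2 = 0.0; }
          if (f3 < 0) { f3 = 0; t3 = 0.0; }
          if (f1 >= n1 - 1) { f1 = n1 - 1; t1 = 0.0; }
          if (f2 >= n2 - 1) { f2 = n2 - 1; t2 = 0.0; }
          if (f3 >= n3 - 1) { f3 = n3 - 1; t3 = 0.0; }
          const int c1 = std::min(f1 + 1, n1 - 1), c2 = std::min(f2 + 1, n2 - 1),
                    c3 = std::min(f3 + 1, n3 - 1);
          val =
            (1 - t3) * ((1 - t2) * ((1 - t1) * at(v, n1, n2, f1, f2, f3) +
                                    t1 * at(v, n1, n2, c1, f2, f3)) +
                        t2 * ((1 - t1) * at(v, n1, n2, f1, c2, f3) +
                              t1 * at(v, n1, n2, c1, c2, f3))) +
            t3 * ((1 - t2) * ((1 - t1) * at(v, n1, n2, f1, f2, c3) +
                              t1 * at(v, n1, n2, c1, f2, c3)) +
                  t2 * ((1 - t1) * at(v, n1, n2, f1, c2, c3) +
                        t1 * at(v, n1, n2, c1, c2, c3)));
        }
        o[j1 + (std::size_t)m1 * (j2 + (std::size_t)m2 * j3)] = val;
      }
    }
  }
  return out;
}

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher) with
// anisotropic sample positions x_i = i * h.
static void dt1d(const double* f, double* out, int n, double h,
                 std::vector<int>& vbuf, std::vector<double>& zbuf) {
  const double INF = std::numeric_limits<double>::infinity();
  const double h2 = h * h;
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue; // parabolas at infinite height never win
    if (k < 0) {
      k = 0;
      vbuf[0] = q;
      zbuf[0] = -INF;
      continue;
    }
    double s;
    for (;;) {
      const int p = vbuf[k];
      s = ((f[q] + q * (double)q * h2) - (f[p] + p * (double)p * h2)) /
          (2.0 * h * (q - p));
      if (s <= zbuf[k]) {
        if (--k < 0) { k = 0; vbuf[0] = q; zbuf[0] = -INF; s = -INF; break; }
      } else break;
    }
    if (vbuf[k] != q) {
      ++k;
      vbuf[k] = q;
      zbuf[k] = s;
    }
  }
  if (k < 0) { // no finite source in this line
    std::fill(out, out + n, INF);
    return;
  }
  zbuf[k + 1] = INF;
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[j + 1] < q * h) ++j;
    const int p = vbuf[j];
    out[q] = f[p] + (q - p) * (double)(q - p) * h2;
  }
}

// Squared EDT (mm^2) of a feature mask: distance from every voxel center to
// the nearest feature voxel center. Empty mask -> all Inf.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, NumericVector spacing) {
  IntegerVector d = mask.attr("dim");
  const int n1 = d[0], n2 = d[1], n3 = d[2];
  NumericVector out(mask.size());
  out.attr("dim") = d;
  double* D = out.begin();
  const int* m = mask.begin();
  const double INF = std::numeric_limits<double>::infinity();
  for (std::size_t i = 0; i < (std::size_t)mask.size(); ++i)
    D[i] = m[i] ? 0.0 : INF;
  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), g(nmax), zbuf(nmax + 1);
  std::vector<int> vbuf(nmax);

  // axis 1
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2) {
      double* row = D + (std::size_t)n1 * (i2 + (std::size_t)n2 * i3);
      dt1d(row, g.data(), n1, spacing[0], vbuf, zbuf);
      std::copy(g.data(), g.data() + n1, row);
    }
  // axis 2
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i1 = 0; i1 < n1; ++i1) {
      for (int i2 = 0; i2 < n2; ++i2)
        f[i2] = D[i1 + (std::size_t)n1 * (i2 + (std::size_t)n2 * i3)];
      dt1d(f.data(), g.data(), n2, spacing[1], vbuf, zbuf);
      for (int i2 = 0; i2 < n2; ++i2)
        D[i1 + (std::size_t)n1 * (i2 + (std::size_t)n2 * i3)] = g[i2];
    }
  // axis 3
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1) {
      for (int i3 = 0; i3 < n3; ++i3)
        f[i3] = D[i1 + (std::size_t)n1 * (i2 + (std::size_t)n2 * i3)];
      dt1d(f.data(), g.data(), n3, spacing[2], vbuf, zbuf);
      for (int i3 = 0; i3 < n3; ++i3)
        D[i1 + (std::size_t)n1 * (i2 + (std::size_t)n2 * i3)] = g[i3];
    }
  return out;
}
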