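// GEMM-based 3D convolution kernels.
//
// Feature tensors are stored channel-fastest: dim = (C, X, Y, Z), column
// major, so one spatial position is a contiguous block of C doubles.
// Weights for a k-kernel conv are a (Cout x C*kx*ky*kz) matrix whose column
// index runs channel fastest, then dx, dy, dz. Output z-slabs are processed
// in chunks so the im2col buffer stays below ~256 MB regardless of geometry.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double COL_BUDGET = 32e6; // doubles per im2col buffer

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// valid output range [lo, hi] along one axis for a given kernel offset:
// input index i = o*s - p + d must satisfy 0 <= i < n
static inline void valid_range(int n, int no, int s, int p, int d,
                               int& lo, int& hi) {
  lo = (p - d + s - 1) / s;       // ceil((p - d) / s)
  if (p - d <= 0) lo = 0;
  hi = (n - 1 + p - d) / s;       // floor((n - 1 + p - d) / s)
  if (hi > no - 1) hi = no - 1;
}

// fill im2col buffer for output slab [z0, z1); the inner loop runs over
// contiguous output-x stretches so bounds checks stay out of the hot path
static void im2col_slab(const double* x, int C, int X, int Y, int Z,
                        int kx, int ky, int kz, int sx, int sy, int sz,
                        int px, int py, int pz, int Xo, int Yo,
                        int z0, int z1, arma::mat& col) {
  const std::size_t CK = (std::size_t)C * kx * ky * kz;
  std::fill(col.memptr(), col.memptr() + col.n_elem, 0.0);
  int xlo, xhi;
  for (int oz = z0; oz < z1; ++oz)
    for (int dz = 0; dz < kz; ++dz) {
      const int iz = oz * sz - pz + dz;
      if (iz < 0 || iz >= Z) continue;
      for (int oy = 0; oy < Yo; ++oy)
        for (int dy = 0; dy < ky; ++dy) {
          const int iy = oy * sy - py + dy;
          if (iy < 0 || iy >= Y) continue;
          const double* xrow =
            x + (std::size_t)C * ((std::size_t)X * (iy + (std::size_t)Y * iz));
          for (int dx = 0; dx < kx; ++dx) {
            valid_range(X, Xo, sx, px, dx, xlo, xhi);
            if (xlo > xhi) continue;
            const std::size_t row0 =
              (std::size_t)C * (dx + kx * (dy + (std::size_t)ky * dz));
            double* dst = col.colptr((std::size_t)xlo + (std::size_t)Xo *
                                     (oy + (std::size_t)Yo * (oz - z0))) + row0;
            const double* src = xrow + (std::size_t)C * (xlo * sx - px + dx);
            for (int ox = xlo; ox <= xhi; ++ox) {
              std::copy(src, src + C, dst);
              dst += CK;
              src += (std::size_t)C * sx;
            }
          }
        }
    }
}

// scatter-add inverse of im2col_slab
static void col2im_slab(const arma::mat& col, double* gx,
                        int C, int X, int Y, int Z,
                        int kx, int ky, int kz, int sx, int sy, int sz,
                        int px, int py, int pz, int Xo, int Yo,
                        int z0, int z1) {
  const std::size_t CK = (std::size_t)C * kx * ky * kz;
  int xlo, xhi;
  for (int oz = z0; oz < z1; ++oz)
    for (int dz = 0; dz < kz; ++dz) {
      const int iz = oz * sz - pz + dz;
      if (iz < 0 || iz >= Z) continue;
      for (int oy = 0; oy < Yo; ++oy)
        for (int dy = 0; dy < ky; ++dy) {
          const int iy = oy * sy - py + dy;
          if (iy < 0 || iy >= Y) continue;
          double* grow =
            gx + (std::size_t)C * ((std::size_t)X * (iy + (std::size_t)Y * iz));
          for (int dx = 0; dx < kx; ++dx) {
            valid_range(X, Xo, sx, px, dx, xlo, xhi);
            if (xlo > xhi) continue;
            const std::size_t row0 =
              (std::size_t)C * (dx + kx * (dy + (std::size_t)ky * dz));
            const double* src = col.colptr((std::size_t)xlo + (std::size_t)Xo *
                                           (oy + (std::size_t)Yo * (oz - z0))) + row0;
            double* dst = grow + (std::size_t)C * (xlo * sx - px + dx);
            for (int ox = xlo; ox <= xhi; ++ox) {
              for (int c = 0; c < C; ++c) dst[c] += src[c];
              src += CK;
              dst += (std::size_t)C * sx;
            }
          }
        }
    }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                             IntegerVector kdim, IntegerVector stride,
                             IntegerVector pad) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int px = pad[0], py = pad[1], pz = pad[2];
  const int Xo = out_size(X, kx, sx, px), Yo = out_size(Y, ky, sy, py),
            Zo = out_size(Z, kz, sz, pz);
  const int Cout = w.nrow(), CK = w.ncol();
  if (CK != C * kx * ky * kz) stop("weight shape does not match input channels/kernel");

  NumericVector out((std::size_t)Cout * Xo * Yo * Zo);
  out.attr("dim") = IntegerVector::create(Cout, Xo, Yo, Zo);
  arma::mat W(w.begin(), Cout, CK, false);
  arma::vec bias(b.begin(), Cout, false);

  int slab = std::max(1, (int)(COL_BUDGET / ((double)CK * Xo * Yo)));
  arma::mat col(CK, (std::size_t)Xo * Yo * std::min(slab, Zo));
  for (int z0 = 0; z0 < Zo; z0 += slab) {
    const int z1 = std::min(Zo, z0 + slab);
    const std::size_t n = (std::size_t)Xo * Yo * (z1 - z0);
    if (col.n_cols != n) col.set_size(CK, n);
    im2col_slab(x.begin(), C, X, Y, Z, kx, ky, kz, sx, sy, sz, px, py, pz,
                Xo, Yo, z0, z1, col);
    arma::mat o(out.begin() + (std::size_t)Cout * Xo * Yo * z0, Cout, n, false, true);
    o = W * col;
    o.each_col() += bias;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericMatrix w, NumericVector gout,
                    IntegerVector kdim, IntegerVector stride, IntegerVector pad) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  IntegerVector od = gout.attr("dim");
  const int Cout = od[0], Xo = od[1], Yo = od[2], Zo = od[3];
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int px = pad[0], py = pad[1], pz = pad[2];
  const int CK = C * kx * ky * kz;

  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  arma::mat W(w.begin(), Cout, CK, false);
  arma::mat gW(Cout, CK, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);

  int slab = std::max(1, (int)(COL_BUDGET / ((double)CK * Xo * Yo)));
  arma::mat col(CK, (std::size_t)Xo * Yo * std::min(slab, Zo));
  for (int z0 = 0; z0 < Zo; z0 += slab) {
    const int z1 = std::min(Zo, z0 + slab);
    const std::size_t n = (std::size_t)Xo * Yo * (z1 - z0);
    if (col.n_cols != n) col.set_size(CK, n);
    im2col_slab(x.begin(), C, X, Y, Z, kx, ky, kz, sx, sy, sz, px, py, pz,
                Xo, Yo, z0, z1, col);
    arma::mat go(gout.begin() + (std::size_t)Cout * Xo * Yo * z0, Cout, n, false, true);
    gW += go * col.t();
    gb += arma::sum(go, 1);
    col = W.t() * go; // reuse buffer for gradient columns
    col2im_slab(col, gx.begin(), C, X, Y, Z, kx, ky, kz, sx, sy, sz,
                px, py, pz, Xo, Yo, z0, z1);
  }
  return List::create(_["gx"] = gx, _["gw"] = wrap(gW), _["gb"] = wrap(gb));
}

// Transposed conv with kernel == stride (non-overlapping learned upsample).
// Weights: (Cout*fx*fy*fz) x Cin, row index channel fastest then dx, dy, dz.

// [[Rcpp::export]]
NumericVector cpp_convt3d_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                              IntegerVector factor) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  const int fx = factor[0], fy = factor[1], fz = factor[2];
  const int K = fx * fy * fz;
  const int Cout = w.nrow() / K;
  const std::size_t N = (std::size_t)X * Y * Z;
  arma::mat xm(x.begin(), C, N, false);
  arma::mat W(w.begin(), Cout * K, C, false);
  arma::mat cols = W * xm; // (Cout*K) x N

  const int Xo = X * fx, Yo = Y * fy, Zo = Z * fz;
  NumericVector out((std::size_t)Cout * Xo * Yo * Zo);
  out.attr("dim") = IntegerVector::create(Cout, Xo, Yo, Zo);
  double* o = out.begin();
  for (int iz = 0; iz < Z; ++iz)
    for (int iy = 0; iy < Y; ++iy)
      for (int ix = 0; ix < X; ++ix) {
        const double* cj = cols.colptr((std::size_t)ix + (std::size_t)X * (iy + (std::size_t)Y * iz));
        for (int dz = 0; dz < fz; ++dz)
          for (int dy = 0; dy < fy; ++dy)
            for (int dx = 0; dx < fx; ++dx) {
              double* dst = o + (std::size_t)Cout *
                ((ix * fx + dx) + (std::size_t)Xo * ((iy * fy + dy) + (std::size_t)Yo * (iz * fz + dz)));
              const double* src = cj + (std::size_t)Cout * (dx + fx * (dy + (std::size_t)fy * dz));
              for (int c = 0; c < Cout; ++c) dst[c] = src[c];
            }
      }
  // add bias
  for (std::size_t j = 0; j < (std::size_t)Xo * Yo * Zo; ++j)
    for (int c = 0; c < Cout; ++c) o[(std::size_t)Cout * j + c] += b[c];
  return out;
}

// [[Rcpp::export]]
List cpp_convt3d_bwd(NumericVector x, NumericMatrix w, NumericVector gout,
                     IntegerVector factor) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  const int fx = factor[0], fy = factor[1], fz = factor[2];
  const int K = fx * fy * fz;
  const int Cout = w.nrow() / K;
  const int Xo = X * fx, Yo = Y * fy, Zo = Z * fz;
  const std::size_t N = (std::size_t)X * Y * Z;

  // gather gout into (Cout*K) x N column layout matching forward
  arma::mat gcols(Cout * K, N);
  const double* go = gout.begin();
  arma::vec gb(Cout, arma::fill::zeros);
  for (int iz = 0; iz < Z; ++iz)
    for (int iy = 0; iy < Y; ++iy)
      for (int ix = 0; ix < X; ++ix) {
        double* cj = gcols.colptr((std::size_t)ix + (std::size_t)X * (iy + (std::size_t)Y * iz));
        for (int dz = 0; dz < fz; ++dz)
          for (int dy = 0; dy < fy; ++dy)
            for (int dx = 0; dx < fx; ++dx) {
              const double* src = go + (std::size_t)Cout *
                ((ix * fx + dx) + (std::size_t)Xo * ((iy * fy + dy) + (std::size_t)Yo * (iz * fz + dz)));
              double* dst = cj + (std::size_t)Cout * (dx + fx * (dy + (std::size_t)fy * dz));
              std::copy(src, src + Cout, dst);
            }
      }
  for (std::size_t j = 0; j < (std::size_t)Xo * Yo * Zo; ++j)
    for (int c = 0; c < Cout; ++c) gb[c] += go[(std::size_t)Cout * j + c];

  arma::mat xm(x.begin(), C, N, false);
  arma::mat W(w.begin(), Cout * K, C, false);
  arma::mat gW = gcols * xm.t();
  arma::mat gxm = W.t() * gcols;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  std::copy(gxm.memptr(), gxm.memptr() + gxm.n_elem, gx.begin());
  return List::create(_["gx"] = gx, _["gw"] = wrap(gW), _["gb"] = wrap(gb));
}

// Max pooling by integer factors, recording argmax for the backward pass.

// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x, IntegerVector factor) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  const int fx = factor[0], fy = factor[1], fz = factor[2];
  const int Xo = X / fx, Yo = Y / fy, Zo = Z / fz;
  NumericVector out((std::size_t)C * Xo * Yo * Zo);
  out.attr("dim") = IntegerVector::create(C, Xo, Yo, Zo);
  IntegerVector arg(out.size());
  const double* xi = x.begin();
  double* o = out.begin();
  int* a = arg.begin();
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox)
        for (int c = 0; c < C; ++c) {
          double best = -std::numeric_limits<double>::infinity();
          std::size_t besti = 0;
          for (int dz = 0; dz < fz; ++dz)
            for (int dy = 0; dy < fy; ++dy)
              for (int dx = 0; dx < fx; ++dx) {
                const std::size_t idx = c + (std::size_t)C *
                  ((ox * fx + dx) + (std::size_t)X * ((oy * fy + dy) + (std::size_t)Y * (oz * fz + dz)));
                if (xi[idx] > best) { best = xi[idx]; besti = idx; }
              }
          const std::size_t j = c + (std::size_t)C * (ox + (std::size_t)Xo * (oy + (std::size_t)Yo * oz));
          o[j] = best;
          a[j] = (int)besti;
        }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector gout, IntegerVector argmax,
                                IntegerVector xdim) {
  std::size_t n = (std::size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  const double* go = gout.begin();
  double* g = gx.begin();
  const int* a = argmax.begin();
  for (R_xlen_t j = 0; j < gout.size(); ++j) g[a[j]] += go[j];
  return gx;
}

// 26-connectivity connected components on a binary 3D mask (dim n1,n2,n3).

// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask) {
  IntegerVector d = mask.attr("dim");
  const int n1 = d[0], n2 = d[1], n3 = d[2];
  IntegerVector lab(mask.size());
  lab.attr("dim") = d;
  const int* m = mask.begin();
  int* L = lab.begin();
  std::vector<std::size_t> stack;
  int cur = 0;
  for (std::size_t i = 0; i < (std::size_t)mask.size(); ++i) {
    if (!m[i] || L[i]) continue;
    ++cur;
    stack.push_back(i);
    L[i] = cur;
    while (!stack.empty()) {
      const std::size_t v = stack.back(); stack.pop_back();
      const int i1 = v % n1, i2 = (v / n1) % n2, i3 = v / ((std::size_t)n1 * n2);
      for (int d3 = -1; d3 <= 1; ++d3)
        for (int d2 = -1; d2 <= 1; ++d2)
          for (int d1 = -1; d1 <= 1; ++d1) {
            const int j1 = i1 + d1, j2 = i2 + d2, j3 = i3 + d3;
            if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3)
              continue;
            const std::size_t j = j1 + (std::size_t)n1 * (j2 + (std::size_t)n2 * j3);
            if (m[j] && !L[j]) { L[j] = cur; stack.push_back(j); }
          }
    }
  }
  return lab;
}
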