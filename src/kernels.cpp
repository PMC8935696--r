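#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Array layout: column-major R arrays, dims (nx, ny, nz[, c]).
static inline int idx4(int i, int j, int k, int c, int nx, int ny, int nz) {
  return i + nx * (j + ny * (k + (R_xlen_t)nz * c));
}

// Same-padding 3D convolution. x: (nx,ny,nz,cin); w: (kk,kk,kk,cin,cout); b: cout.
// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         IntegerVector xdim, int kk, int cin, int cout) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2];
  const int pad = (kk - 1) / 2;
  NumericVector out((R_xlen_t)nx * ny * nz * cout);
  const double *px = x.begin(), *pw = w.begin();
  double *po = out.begin();
  const int kvol = kk * kk * kk;
  for (int co = 0; co < cout; ++co) {
    const double bco = b[co];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double acc = bco;
          for (int ci = 0; ci < cin; ++ci) {
            const double *wc = pw + (R_xlen_t)kvol * (ci + (R_xlen_t)cin * co);
            const double *xc = px + (R_xlen_t)nx * ny * nz * ci;
            for (int dz = 0; dz < kk; ++dz) {
              int zz = k + dz - pad; if (zz < 0 || zz >= nz) continue;
              for (int dy = 0; dy < kk; ++dy) {
                int yy = j + dy - pad; if (yy < 0 || yy >= ny) continue;
                for (int dx = 0; dx < kk; ++dx) {
                  int xx = i + dx - pad; if (xx < 0 || xx >= nx) continue;
                  acc += xc[xx + nx * (yy + (R_xlen_t)ny * zz)] *
                         wc[dx + kk * (dy + kk * dz)];
                }
              }
            }
          }
          po[idx4(i, j, k, co, nx, ny, nz)] = acc;
        }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return out;
}

// Backward pass: gradients w.r.t. input, weights, bias.
// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector gout,
                IntegerVector xdim, int kk, int cin, int cout) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2];
  const int pad = (kk - 1) / 2, kvol = kk * kk * kk;
  NumericVector gx((R_xlen_t)nx * ny * nz * cin);
  NumericVector gw((R_xlen_t)kvol * cin * cout);
  NumericVector gb(cout);
  const double *px = x.begin(), *pw = w.begin(), *pg = gout.begin();
  double *pgx = gx.begin(), *pgw = gw.begin();
  for (int co = 0; co < cout; ++co) {
    double bacc = 0.0;
    const double *gc = pg + (R_xlen_t)nx * ny * nz * co;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const double g = gc[i + nx * (j + (R_xlen_t)ny * k)];
          if (g == 0.0) continue;
          bacc += g;
          for (int ci = 0; ci < cin; ++ci) {
            const double *wc = pw + (R_xlen_t)kvol * (ci + (R_xlen_t)cin * co);
            double *gwc = pgw + (R_xlen_t)kvol * (ci + (R_xlen_t)cin * co);
            const double *xc = px + (R_xlen_t)nx * ny * nz * ci;
            double *gxc = pgx + (R_xlen_t)nx * ny * nz * ci;
            for (int dz = 0; dz < kk; ++dz) {
              int zz = k + dz - pad; if (zz < 0 || zz >= nz) continue;
              for (int dy = 0; dy < kk; ++dy) {
                int yy = j + dy - pad; if (yy < 0 || yy >= ny) continue;
                for (int dx = 0; dx < kk; ++dx) {
                  int xx = i + dx - pad; if (xx < 0 || xx >= nx) continue;
                  const int xi = xx + nx * (yy + (R_xlen_t)ny * zz);
                  const int wi = dx + kk * (dy + kk * dz);
                  gwc[wi] += g * xc[xi];
                  gxc[xi] += g * wc[wi];
                }
              }
            }
          }
        }
    gb[co] = bacc;
  }
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  gw.attr("dim") = IntegerVector::create(kk, kk, kk, cin, cout);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x max pooling over the three spatial axes; records argmax for backprop.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x, IntegerVector xdim, int nc) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2];
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  NumericVector y((R_xlen_t)ox * oy * oz * nc);
  IntegerVector am((R_xlen_t)ox * oy * oz * nc);
  const double *px = x.begin();
  for (int c = 0; c < nc; ++c)
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j)
        for (int i = 0; i < ox; ++i) {
          double best = R_NegInf; int bi = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                int src = idx4(2 * i + dx, 2 * j + dy, 2 * k + dz, c, nx, ny, nz);
                if (px[src] > best) { best = px[src]; bi = src; }
              }
          int o = idx4(i, j, k, c, ox, oy, oz);
          y[o] = best; am[o] = bi;
        }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector gy, IntegerVector argmax,
                           IntegerVector xdim, int nc) {
  NumericVector gx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * nc);
  for (R_xlen_t t = 0; t < gy.size(); ++t) gx[argmax[t]] += gy[t];
  gx.attr("dim") = IntegerVector::create(xdim[0], xdim[1], xdim[2], nc);
  return gx;
}

// Nearest-neighbour 2x upsampling and its adjoint.
// [[Rcpp::export(name = ".upsample2_fwd")]]
NumericVector upsample2_fwd(NumericVector x, IntegerVector xdim, int nc) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  NumericVector y((R_xlen_t)ox * oy * oz * nc);
  const double *px = x.begin();
  for (int c = 0; c < nc; ++c)
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j)
        for (int i = 0; i < ox; ++i)
          y[idx4(i, j, k, c, ox, oy, oz)] =
            px[idx4(i / 2, j / 2, k / 2, c, nx, ny, nz)];
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
NumericVector upsample2_bwd(NumericVector gy, IntegerVector ydim, int nc) {
  const int ox = ydim[0], oy = ydim[1], oz = ydim[2];
  const int nx = ox / 2, ny = oy / 2, nz = oz / 2;
  NumericVector gx((R_xlen_t)nx * ny * nz * nc);
  const double *pg = gy.begin();
  for (int c = 0; c < nc; ++c)
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j)
        for (int i = 0; i < ox; ++i)
          gx[idx4(i / 2, j / 2, k / 2, c, nx, ny, nz)] +=
            pg[idx4(i, j, k, c, ox, oy, oz)];
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return gx;
}

// Connected components on a 3D (or 2D with nz = 1) binary array, 26-connectivity.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  IntegerVector lab((R_xlen_t)nx * ny * nz);
  int next = 0;
  std::queue<int> q;
  for (R_xlen_t s = 0; s < lab.size(); ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push((int)s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int ii = i + dx, jj = j + dy, kk = k + dz;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            int u = ii + nx * (jj + ny * kk);
            if (mask[u] && lab[u] == 0) { lab[u] = next; q.push(u); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Resample src onto a dst grid under an affine world map (dst -> src world),
// world coordinates centred on each volume: w = (index - (n+1)/2) * spacing.
// A is 3x3 row-major-flattened column matrix from R (we index A[r + 3*c]).
// [[Rcpp::export(name = ".resample_affine")]]
NumericVector resample_affine(NumericVector src, NumericVector src_spacing,
                              IntegerVector src_dim, IntegerVector dst_dim,
                              NumericVector dst_spacing, NumericMatrix A,
                              NumericVector t, bool nearest, double fill) {
  const int sx = src_dim[0], sy = src_dim[1], sz = src_dim[2];
  const int dx = dst_dim[0], dy = dst_dim[1], dz = dst_dim[2];
  NumericVector out((R_xlen_t)dx * dy * dz, fill);
  const double *ps = src.begin();
  double *po = out.begin();
  const double cxs = (sx + 1) / 2.0, cys = (sy + 1) / 2.0, czs = (sz + 1) / 2.0;
  const double cxd = (dx + 1) / 2.0, cyd = (dy + 1) / 2.0, czd = (dz + 1) / 2.0;
  for (int k = 0; k < dz; ++k)
    for (int j = 0; j < dy; ++j)
      for (int i = 0; i < dx; ++i) {
        double wx = (i + 1 - cxd) * dst_spacing[0];
        double wy = (j + 1 - cyd) * dst_spacing[1];
        double wz = (k + 1 - czd) * dst_spacing[2];
        double ux = A(0, 0) * wx + A(0, 1) * wy + A(0, 2) * wz + t[0];
        double uy = A(1, 0) * wx + A(1, 1) * wy + A(1, 2) * wz + t[1];
        double uz = A(2, 0) * wx + A(2, 1) * wy + A(2, 2) * wz + t[2];
        double fi = ux / src_spacing[0] + cxs - 1.0;  // 0-based src index
        double fj = uy / src_spacing[1] + cys - 1.0;
        double fk = uz / src_spacing[2] + czs - 1.0;
        R_xlen_t o = i + dx * (j + (R_xlen_t)dy * k);
        if (nearest) {
          int ii = (int)std::lround(fi), jj = (int)std::lround(fj),
              kk = (int)std::lround(fk);
          if (ii < 0 || ii >= sx || jj < 0 || jj >= sy || kk < 0 || kk >= sz)
            continue;
          po[o] = ps[ii + sx * (jj + (R_xlen_t)sy * kk)];
        } else {
          int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj),
              k0 = (int)std::floor(fk);
          if (i0 < 0 || i0 + 1 >= sx || j0 < 0 || j0 + 1 >= sy ||
              k0 < 0 || k0 + 1 >= sz)
            continue;
          double ai = fi - i0, aj = fj - j0, ak = fk - k0;
          double acc = 0.0;
          for (int bz = 0; bz < 2; ++bz)
            for (int by = 0; by < 2; ++by)
              for (int bx = 0; bx < 2; ++bx) {
                double wgt = (bx ? ai : 1 - ai) * (by ? aj : 1 - aj) *
                             (bz ? ak : 1 - ak);
                acc += wgt * ps[(i0 + bx) + sx * ((j0 + by) + (R_xlen_t)sy * (k0 + bz))];
              }
          po[o] = acc;
        }
      }
  out.attr("dim") = dst_dim;
  return out;
}
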