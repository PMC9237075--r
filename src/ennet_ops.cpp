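#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cstring>
#include <limits>
#include <vector>
using namespace Rcpp;

// Feature tensors are V x C matrices: V = nx*ny*nz voxels in column-major
// spatial order (x fastest), C channels. All indices 0-based internally.

// ---- 3x3x3 convolution (padding 1, stride 1) ---------------------------
//
// Realised as 27 offset-blocked GEMMs: Y = sum_o shift_o(X) %*% W_o + b,
// where offset o = (dx+1) + 3*(dy+1) + 9*(dz+1), d* in {-1,0,1}, and the
// weight matrix W is (27*C_in) x C_out with row index o*C_in + c. A single
// V x C_in buffer holds the shifted view, so no im2col matrix is ever
// materialised.

// copy X shifted by (dx,dy,dz) into buf, zero outside the grid
static void shift_copy(const double* x, double* buf, int V, int C,
                       int nx, int ny, int nz, int dx, int dy, int dz) {
  std::memset(buf, 0, (size_t)V * C * sizeof(double));
  const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
  const int run = x1 - x0;
  if (run <= 0) return;
  const int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
  const int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * V;
    double* bc = buf + (size_t)c * V;
    for (int iz = z0; iz < z1; ++iz)
      for (int iy = y0; iy < y1; ++iy) {
        const int dst = x0 + nx * (iy + ny * iz);
        const int src = (x0 + dx) + nx * ((iy + dy) + ny * (iz + dz));
        std::memcpy(bc + dst, xc + src, run * sizeof(double));
      }
  }
}

// accumulate t shifted by (dx,dy,dz) into out: out(v + off) += t(v)
static void shift_add(const double* t, double* out, int V, int C,
                      int nx, int ny, int nz, int dx, int dy, int dz) {
  const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
  const int run = x1 - x0;
  if (run <= 0) return;
  const int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
  const int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
  for (int c = 0; c < C; ++c) {
    const double* tc = t + (size_t)c * V;
    double* oc = out + (size_t)c * V;
    for (int iz = z0; iz < z1; ++iz)
      for (int iy = y0; iy < y1; ++iy) {
        const int dst = x0 + nx * (iy + ny * iz);       // position of v
        const int src = (x0 + dx) + nx * ((iy + dy) + ny * (iz + dz));
        // out(v + off) += t(v): v runs over the dst window, v+off over src
        for (int i = 0; i < run; ++i) oc[src + i] += tc[dst + i];
      }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3_fwd(const NumericMatrix& x, int nx, int ny, int nz,
                            const NumericMatrix& W, const NumericVector& b) {
  const int V = nx * ny * nz, C = x.ncol(), Cout = W.ncol();
  if (x.nrow() != V) stop("conv3: voxel count mismatch");
  if (W.nrow() != 27 * C) stop("conv3: weight rows must be 27*C_in");
  NumericMatrix y(V, Cout);
  for (int c = 0; c < Cout; ++c)
    std::fill(&y(0, c), &y(0, c) + V, b[c]);
  std::vector<double> buf((size_t)V * C);
  const double one = 1.0;
  const int ldw = 27 * C;
  for (int o = 0; o < 27; ++o) {
    const int dx = o % 3 - 1, dy = (o / 3) % 3 - 1, dz = o / 9 - 1;
    const double* A;
    if (dx == 0 && dy == 0 && dz == 0) A = &x(0, 0);
    else {
      shift_copy(&x(0, 0), buf.data(), V, C, nx, ny, nz, dx, dy, dz);
      A = buf.data();
    }
    F77_CALL(dgemm)("N", "N", &V, &Cout, &C, &one, A, &V,
                    &W(o * C, 0), &ldw, &one, &y(0, 0), &V FCONE FCONE);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(const NumericMatrix& x, const NumericMatrix& dy,
                   int nx, int ny, int nz, const NumericMatrix& W) {
  const int V = nx * ny * nz, C = x.ncol(), Cout = W.ncol();
  if (dy.nrow() != V || dy.ncol() != Cout) stop("conv3 bwd: shape mismatch");
  NumericMatrix dW(27 * C, Cout), dxm(V, C);
  NumericVector db(Cout);
  for (int c = 0; c < Cout; ++c) {
    double s = 0;
    const double* col = &dy(0, c);
    for (int i = 0; i < V; ++i) s += col[i];
    db[c] = s;
  }
  std::vector<double> buf((size_t)V * C), tbuf((size_t)V * C);
  const double one = 1.0, zero = 0.0;
  const int ldw = 27 * C;
  for (int o = 0; o < 27; ++o) {
    const int dx = o % 3 - 1, dy_ = (o / 3) % 3 - 1, dz = o / 9 - 1;
    const bool centre = (dx == 0 && dy_ == 0 && dz == 0);
    const double* A;
    if (centre) A = &x(0, 0);
    else {
      shift_copy(&x(0, 0), buf.data(), V, C, nx, ny, nz, dx, dy_, dz);
      A = buf.data();
    }
    // dW_o = shift_o(X)^T %*% dY
    F77_CALL(dgemm)("T", "N", &C, &Cout, &V, &one, A, &V, &dy(0, 0), &V,
                    &zero, &dW(o * C, 0), &ldw FCONE FCONE);
    // T_o = dY %*% W_o^T ; dX(v + off_o) += T_o(v)
    F77_CALL(dgemm)("N", "T", &V, &C, &Cout, &one, &dy(0, 0), &V,
                    &W(o * C, 0), &ldw, &zero, tbuf.data(), &V FCONE FCONE);
    if (centre) {
      double* d = &dxm(0, 0);
      const double* t = tbuf.data();
      for (size_t i = 0; i < (size_t)V * C; ++i) d[i] += t[i];
    } else {
      shift_add(tbuf.data(), &dxm(0, 0), V, C, nx, ny, nz, dx, dy_, dz);
    }
  }
  return List::create(_["dx"] = dxm, _["dW"] = dW, _["db"] = db);
}

// ---- leaky ReLU ---------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_lrelu_fwd(const NumericMatrix& x, double slope) {
  NumericMatrix y(x.nrow(), x.ncol());
  const double* xi = &x(0, 0);
  double* yi = &y(0, 0);
  const size_t n = (size_t)x.nrow() * x.ncol();
  for (size_t i = 0; i < n; ++i) yi[i] = xi[i] < 0 ? xi[i] * slope : xi[i];
  return y;
}

// slope > 0, so y < 0 exactly where x < 0: the output doubles as the mask.
// [[Rcpp::export]]
NumericMatrix cpp_lrelu_bwd(const NumericMatrix& dy, const NumericMatrix& y,
                            double slope) {
  NumericMatrix dx(dy.nrow(), dy.ncol());
  const double* g = &dy(0, 0);
  const double* yi = &y(0, 0);
  double* d = &dx(0, 0);
  const size_t n = (size_t)dy.nrow() * dy.ncol();
  for (size_t i = 0; i < n; ++i) d[i] = yi[i] < 0 ? g[i] * slope : g[i];
  return dx;
}

// ---- group normalization -------------------------------------------------

// Channels are split into G contiguous groups; statistics pool voxels and
// channels within a group (population variance).
// [[Rcpp::export]]
List cpp_gn_fwd(const NumericMatrix& x, const NumericVector& gamma,
                const NumericVector& beta, int G, double eps) {
  const int V = x.nrow(), C = x.ncol();
  if (C % G) stop("groupnorm: channels not divisible by groups");
  const int gs = C / G;
  NumericMatrix y(V, C), xhat(V, C);
  NumericVector inv_sd(G);
  for (int g = 0; g < G; ++g) {
    const double* xg = &x(0, g * gs);
    const size_t n = (size_t)V * gs;
    double s = 0, s2 = 0;
    for (size_t i = 0; i < n; ++i) { s += xg[i]; s2 += xg[i] * xg[i]; }
    const double mu = s / n;
    const double var = s2 / n - mu * mu;
    const double inv = 1.0 / std::sqrt(var + eps);
    inv_sd[g] = inv;
    for (int j = 0; j < gs; ++j) {
      const int c = g * gs + j;
      const double* xc = &x(0, c);
      double* hc = &xhat(0, c);
      double* yc = &y(0, c);
      const double ga = gamma[c], be = beta[c];
      for (int i = 0; i < V; ++i) {
        const double h = (xc[i] - mu) * inv;
        hc[i] = h;
        yc[i] = h * ga + be;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv_sd"] = inv_sd);
}

// [[Rcpp::export]]
List cpp_gn_bwd(const NumericMatrix& dy, const NumericMatrix& xhat,
                const NumericVector& inv_sd, const NumericVector& gamma,
                int G) {
  const int V = dy.nrow(), C = dy.ncol();
  const int gs = C / G;
  NumericMatrix dx(V, C);
  NumericVector dgamma(C), dbeta(C);
  std::vector<double> dxh((size_t)V * gs);
  for (int g = 0; g < G; ++g) {
    double m1 = 0, m2 = 0;
    for (int j = 0; j < gs; ++j) {
      const int c = g * gs + j;
      const double* gc = &dy(0, c);
      const double* hc = &xhat(0, c);
      double* dh = dxh.data() + (size_t)j * V;
      const double ga = gamma[c];
      double sg = 0, sb = 0;
      for (int i = 0; i < V; ++i) {
        sg += gc[i] * hc[i];
        sb += gc[i];
        const double d = gc[i] * ga;
        dh[i] = d;
        m1 += d;
        m2 += d * hc[i];
      }
      dgamma[c] = sg;
      dbeta[c] = sb;
    }
    const size_t n = (size_t)V * gs;
    m1 /= n; m2 /= n;
    const double inv = inv_sd[g];
    for (int j = 0; j < gs; ++j) {
      const int c = g * gs + j;
      const double* hc = &xhat(0, c);
      const double* dh = dxh.data() + (size_t)j * V;
      double* dc = &dx(0, c);
      for (int i = 0; i < V; ++i)
        dc[i] = inv * (dh[i] - m1 - hc[i] * m2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ---- 2x2x2 max pooling (stride 2) -------------------------------------

// [[Rcpp::export]]
List cpp_maxpool_fwd(const NumericMatrix& x, int nx, int ny, int nz) {
  if (nx % 2 || ny % 2 || nz % 2) stop("maxpool: dims must be even");
  const int C = x.ncol();
  const int mx = nx / 2, my = ny / 2, mz = nz / 2, Vo = mx * my * mz;
  NumericMatrix y(Vo, C);
  IntegerMatrix arg(Vo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    for (int iz = 0; iz < mz; ++iz)
      for (int iy = 0; iy < my; ++iy)
        for (int ix = 0; ix < mx; ++ix) {
          double best = -std::numeric_limits<double>::infinity();
          int bidx = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const int s = (2 * ix + dx) + nx * ((2 * iy + dy) + ny * (2 * iz + dz));
                if (xc[s] > best) { best = xc[s]; bidx = s; }
              }
          const int d = ix + mx * (iy + my * iz);
          y(d, c) = best;
          arg(d, c) = bidx;
        }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(const NumericMatrix& dy, const IntegerMatrix& arg,
                              int V) {
  const int C = dy.ncol(), Vo = dy.nrow();
  NumericMatrix dx(V, C);
  for (int c = 0; c < C; ++c)
    for (int i = 0; i < Vo; ++i)
      dx(arg(i, c), c) += dy(i, c);
  return dx;
}

// ---- trilinear x2 upsampling -------------------------------------------

// Half-voxel-aligned sampling: output voxel t maps to source coordinate
// (t + 0.5)/2 - 0.5, clamped to the valid range.
static void up_axis(int n, std::vector<int>& i0, std::vector<int>& i1,
                    std::vector<double>& w1) {
  const int m = 2 * n;
  i0.resize(m); i1.resize(m); w1.resize(m);
  for (int t = 0; t < m; ++t) {
    double s = (t + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > n - 1) s = n - 1;
    int f = (int)std::floor(s);
    if (f > n - 2) f = n - 2;
    if (n == 1) { i0[t] = 0; i1[t] = 0; w1[t] = 0; continue; }
    i0[t] = f; i1[t] = f + 1; w1[t] = s - f;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_upsample_fwd(const NumericMatrix& x, int nx, int ny, int nz) {
  const int C = x.ncol();
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz, Vo = ox * oy * oz;
  std::vector<int> x0, x1, y0, y1, z0, z1;
  std::vector<double> wx, wy, wz;
  up_axis(nx, x0, x1, wx); up_axis(ny, y0, y1, wy); up_axis(nz, z0, z1, wz);
  NumericMatrix out(Vo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    double* oc = &out(0, c);
    for (int iz = 0; iz < oz; ++iz) {
      const double wz1 = wz[iz];
      const int zb0 = ny * z0[iz], zb1 = ny * z1[iz];
      for (int iy = 0; iy < oy; ++iy) {
        const double wy1 = wy[iy];
        const int b00 = nx * (y0[iy] + zb0), b10 = nx * (y1[iy] + zb0);
        const int b01 = nx * (y0[iy] + zb1), b11 = nx * (y1[iy] + zb1);
        double* orow = oc + ox * (iy + oy * iz);
        for (int ix = 0; ix < ox; ++ix) {
          const double w1x = wx[ix], w0x = 1 - w1x;
          const int a = x0[ix], b = x1[ix];
          const double v00 = w0x * xc[a + b00] + w1x * xc[b + b00];
          const double v10 = w0x * xc[a + b10] + w1x * xc[b + b10];
          const double v01 = w0x * xc[a + b01] + w1x * xc[b + b01];
          const double v11 = w0x * xc[a + b11] + w1x * xc[b + b11];
          orow[ix] = (1 - wz1) * ((1 - wy1) * v00 + wy1 * v10) +
                     wz1 * ((1 - wy1) * v01 + wy1 * v11);
        }
      }
    }
  }
  return out;
}

// Exact adjoint of cpp_upsample_fwd; dy is (8V) x C, returns V x C.
// [[Rcpp::export]]
NumericMatrix cpp_upsample_bwd(const NumericMatrix& dy, int nx, int ny, int nz) {
  const int C = dy.ncol();
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  std::vector<int> x0, x1, y0, y1, z0, z1;
  std::vector<double> wx, wy, wz;
  up_axis(nx, x0, x1, wx); up_axis(ny, y0, y1, wy); up_axis(nz, z0, z1, wz);
  NumericMatrix dx(nx * ny * nz, C);
  for (int c = 0; c < C; ++c) {
    const double* gc = &dy(0, c);
    double* dc = &dx(0, c);
    for (int iz = 0; iz < oz; ++iz) {
      const double wz1 = wz[iz];
      const int zb0 = ny * z0[iz], zb1 = ny * z1[iz];
      for (int iy = 0; iy < oy; ++iy) {
        const double wy1 = wy[iy];
        const int b00 = nx * (y0[iy] + zb0), b10 = nx * (y1[iy] + zb0);
        const int b01 = nx * (y0[iy] + zb1), b11 = nx * (y1[iy] + zb1);
        const double* grow = gc + ox * (iy + oy * iz);
        for (int ix = 0; ix < ox; ++ix) {
          const double g = grow[ix];
          if (g == 0) continue;
          const double w1x = wx[ix], w0x = 1 - w1x;
          const int a = x0[ix], b = x1[ix];
          const double c00 = (1 - wz1) * (1 - wy1), c10 = (1 - wz1) * wy1;
          const double c01 = wz1 * (1 - wy1), c11 = wz1 * wy1;
          dc[a + b00] += g * c00 * w0x; dc[b + b00] += g * c00 * w1x;
          dc[a + b10] += g * c10 * w0x; dc[b + b10] += g * c10 * w1x;
          dc[a + b01] += g * c01 * w0x; dc[b + b01] += g * c01 * w1x;
          dc[a + b11] += g * c11 * w0x; dc[b + b11] += g * c11 * w1x;
        }
      }
    }
  }
  return dx;
}

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) --

// Lower envelope of parabolas f[q] + h^2 (x - q)^2; non-site cells carry a
// large finite sentinel instead of infinity so intersections stay finite.
static const double EDT_BIG = 1e12;

static void dt1d(const double* f, int n, double h, double* d,
                 std::vector<int>& v, std::vector<double>& z) {
  v.resize(n); z.resize(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * (double)v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
      if (k > 0 && s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    const double dq = h * (q - v[kk]);
    d[q] = dq * dq + f[v[kk]];
  }
}

// Squared EDT of `sites` (TRUE voxels are distance 0) on an nx*ny*nz grid
// with physical spacing (sx, sy, sz) mm. Returns distances in mm.
// [[Rcpp::export]]
NumericVector cpp_edt(const LogicalVector& sites, int nx, int ny, int nz,
                      double sx, double sy, double sz) {
  const int V = nx * ny * nz;
  if (sites.size() != V) stop("edt: size mismatch");
  std::vector<double> d(V);
  for (int i = 0; i < V; ++i) d[i] = sites[i] ? 0.0 : EDT_BIG;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax);
  std::vector<int> v;
  std::vector<double> z;

  // pass along x
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      double* row = &d[nx * (iy + ny * iz)];
      dt1d(row, nx, sx, out.data(), v, z);
      std::memcpy(row, out.data(), nx * sizeof(double));
    }
  // pass along y
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      for (int iy = 0; iy < ny; ++iy) f[iy] = d[ix + nx * (iy + ny * iz)];
      dt1d(f.data(), ny, sy, out.data(), v, z);
      for (int iy = 0; iy < ny; ++iy) d[ix + nx * (iy + ny * iz)] = out[iy];
    }
  // pass along z
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      for (int iz = 0; iz < nz; ++iz) f[iz] = d[ix + nx * (iy + ny * iz)];
      dt1d(f.data(), nz, sz, out.data(), v, z);
      for (int iz = 0; iz < nz; ++iz) d[ix + nx * (iy + ny * iz)] = out[iz];
    }

  NumericVector res(V);
  for (int i = 0; i < V; ++i) res[i] = std::sqrt(d[i]);
  return res;
}

// 6-connectivity boundary of a binary mask (voxels of the mask with at
// least one face neighbour outside it; grid edges count as outside).
// [[Rcpp::export]]
LogicalVector cpp_boundary(const LogicalVector& mask, int nx, int ny, int nz) {
  const int V = nx * ny * nz;
  if (mask.size() != V) stop("boundary: size mismatch");
  LogicalVector out(V);
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        const int i = ix + nx * (iy + ny * iz);
        if (!mask[i]) continue;
        bool b = ix == 0 || ix == nx - 1 || iy == 0 || iy == ny - 1 ||
                 iz == 0 || iz == nz - 1;
        if (!b) {
          b = !mask[i - 1] || !mask[i + 1] || !mask[i - nx] || !mask[i + nx] ||
              !mask[i - nx * ny] || !mask[i + nx * ny];
        }
        out[i] = b;
      }
  return out;
}
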