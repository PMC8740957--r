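// Low-level numerical kernels: 3D convolution (im2col + BLAS GEMM), max-pooling,
// nearest-neighbour up-sampling, trilinear warping/sampling and their adjoints,
// and separable 1-D convolution with zero extension.
//
// Tensor layouts (all column-major R arrays):
//   feature maps  X : dim (C, d1, d2, d3)        channels fastest
//   conv weights  W : dim (Cout, Cin, k, k, k)   odd k, same zero padding
//   volumes          : dim (d1, d2, d3)
//   displacement     : dim (o1, o2, o3, 3)       voxel units, fixed grid

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline R_xlen_t vox3(int x, int y, int z, int d1, int d2) {
  return (R_xlen_t)x + (R_xlen_t)d1 * ((R_xlen_t)y + (R_xlen_t)d2 * z);
}

// Fill the im2col buffer A (Cin*k^3 rows) for output z-slab [z0, z0+zc).
// Column-major fill: each output voxel writes its patch rows contiguously.
// Single precision: convolutions run in float32 (ample for network training
// and inference); all other kernels stay in double.
static void im2col_slab(const float* X, int Cin, int d1, int d2, int d3,
                        int k, int z0, int zc, arma::fmat& A) {
  const int h = k / 2;
  const size_t cb = sizeof(float) * Cin;
  float* Ap = A.memptr();
  const R_xlen_t R = A.n_rows;
  for (int zz = 0; zz < zc; ++zz) {
    for (int y = 0; y < d2; ++y) {
      for (int x = 0; x < d1; ++x) {
        float* a = Ap + R * ((R_xlen_t)x + (R_xlen_t)d1 * (y + (R_xlen_t)d2 * zz));
        const bool xin = (x >= h && x + h < d1);
        for (int kz = 0; kz < k; ++kz) {
          const int sz = z0 + zz + kz - h;
          if (sz < 0 || sz >= d3) {
            std::memset(a, 0, cb * k * k); a += (R_xlen_t)Cin * k * k; continue;
          }
          for (int ky = 0; ky < k; ++ky) {
            const int sy = y + ky - h;
            if (sy < 0 || sy >= d2) {
              std::memset(a, 0, cb * k); a += (R_xlen_t)Cin * k; continue;
            }
            const float* xrow = X + (R_xlen_t)Cin * vox3(0, sy, sz, d1, d2);
            if (xin) { // whole kx run is in bounds and contiguous in memory
              std::memcpy(a, xrow + (R_xlen_t)Cin * (x - h), cb * k);
              a += (R_xlen_t)Cin * k;
            } else {
              for (int kx = 0; kx < k; ++kx, a += Cin) {
                const int sx = x + kx - h;
                if (sx < 0 || sx >= d1) std::memset(a, 0, cb);
                else std::memcpy(a, xrow + (R_xlen_t)Cin * sx, cb);
              }
            }
          }
        }
      }
    }
  }
}

static int slab_size(int rows, int d1, int d2) {
  // target an im2col slab small enough to stay cache-resident
  double per_slice = (double)rows * d1 * d2;
  int zc = (int)std::max(1.0, std::floor(2e6 / per_slice));
  return zc;
}

// reusable scratch storage: one allocation amortized over all conv calls
static float* scratch_floats(size_t n) {
  static std::vector<float> buf;
  if (buf.size() < n) buf.resize(n);
  return buf.data();
}

static arma::fvec to_float(const double* x, R_xlen_t n) {
  arma::fvec out(n);
  float* o = out.memptr();
  for (R_xlen_t i = 0; i < n; ++i) o[i] = (float)x[i];
  return out;
}

// Same-padding correlation: Y (Cout x N) = Wm (Cout x Cin*k^3) * im2col(X).
static void conv3_run(const float* X, int Cin, int d1, int d2, int d3,
                      const arma::fmat& Wm, int k, const float* bias,
                      float* Y) {
  const int Cout = Wm.n_rows;
  const int R = Cin * k * k * k;
  const int zch = std::min(slab_size(R, d1, d2), d3);
  arma::fmat A(scratch_floats((size_t)R * d1 * d2 * zch), R,
               (R_xlen_t)d1 * d2 * zch, false, true);
  for (int z0 = 0; z0 < d3; z0 += zch) {
    const int zc = std::min(zch, d3 - z0);
    const R_xlen_t ncol = (R_xlen_t)d1 * d2 * zc;
    im2col_slab(X, Cin, d1, d2, d3, k, z0, zc, A);
    arma::fmat Ym(Y + (R_xlen_t)Cout * d1 * d2 * z0, Cout, ncol, false, true);
    if ((R_xlen_t)A.n_cols == ncol) Ym = Wm * A; else Ym = Wm * A.cols(0, ncol - 1);
    if (bias)
      for (R_xlen_t c = 0; c < ncol; ++c) {
        float* y = Ym.colptr(c);
        for (int co = 0; co < Cout; ++co) y[co] += bias[co];
      }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector c_conv3_fw(NumericVector X, IntegerVector xdim,
                         NumericVector W, IntegerVector wdim,
                         NumericVector bias) {
  const int Cin = xdim[0], d1 = xdim[1], d2 = xdim[2], d3 = xdim[3];
  const int Cout = wdim[0], k = wdim[2];
  if (wdim[1] != Cin) stop("weight/input channel mismatch");
  const R_xlen_t N = (R_xlen_t)d1 * d2 * d3;
  const arma::fvec Xf = to_float(X.begin(), (R_xlen_t)Cin * N);
  const arma::fvec Wfv = to_float(W.begin(), W.size());
  const arma::fvec bf = to_float(bias.begin(), bias.size());
  const arma::fmat Wm(const_cast<float*>(Wfv.memptr()), Cout, Cin * k * k * k,
                      false, true);
  arma::fvec Yf((R_xlen_t)Cout * N);
  conv3_run(Xf.memptr(), Cin, d1, d2, d3, Wm, k, bf.memptr(), Yf.memptr());
  NumericVector Y((R_xlen_t)Cout * N);
  for (R_xlen_t i = 0; i < Y.size(); ++i) Y[i] = Yf[i];
  return Y;
}

// [[Rcpp::export(rng = false)]]
List c_conv3_bw(NumericVector X, IntegerVector xdim,
                NumericVector W, IntegerVector wdim,
                NumericVector dY, bool need_dx) {
  const int Cin = xdim[0], d1 = xdim[1], d2 = xdim[2], d3 = xdim[3];
  const int Cout = wdim[0], k = wdim[2];
  const int k3 = k * k * k, R = Cin * k3;
  const R_xlen_t N = (R_xlen_t)d1 * d2 * d3;
  const arma::fvec Xf = to_float(X.begin(), (R_xlen_t)Cin * N);
  const arma::fvec dYf = to_float(dY.begin(), (R_xlen_t)Cout * N);
  // dW and db: dW = dY * im2col(X)^T, slab by slab
  arma::fmat dWm(Cout, R, arma::fill::zeros);
  NumericVector db(Cout);
  {
    const int zch = std::min(slab_size(R, d1, d2), d3);
    arma::fmat A(scratch_floats((size_t)R * d1 * d2 * zch), R,
                 (R_xlen_t)d1 * d2 * zch, false, true);
    for (int z0 = 0; z0 < d3; z0 += zch) {
      const int zc = std::min(zch, d3 - z0);
      const R_xlen_t ncol = (R_xlen_t)d1 * d2 * zc;
      im2col_slab(Xf.memptr(), Cin, d1, d2, d3, k, z0, zc, A);
      arma::fmat dYm(const_cast<float*>(dYf.memptr()) + (R_xlen_t)Cout * d1 * d2 * z0,
                     Cout, ncol, false, true);
      if ((R_xlen_t)A.n_cols == ncol) dWm += dYm * A.t();
      else dWm += dYm * A.cols(0, ncol - 1).t();
      for (R_xlen_t c = 0; c < ncol; ++c) {
        const float* y = dYm.colptr(c);
        for (int co = 0; co < Cout; ++co) db[co] += y[co];
      }
    }
  }
  NumericVector dW((R_xlen_t)Cout * R);
  for (R_xlen_t i = 0; i < dW.size(); ++i) dW[i] = dWm[i];
  if (!need_dx)
    return List::create(_["dX"] = R_NilValue, _["dW"] = dW, _["db"] = db);
  // dX: same-padding correlation of dY with the flipped, channel-transposed
  // kernel (exact adjoint of the forward op for odd k).
  // Wflip[ci, co + Cout*(kx + k*(ky + k*kz))] = W[co, ci, k-1-kx, k-1-ky, k-1-kz]
  arma::fmat Wf(Cin, Cout * k3);
  for (int kz = 0; kz < k; ++kz)
    for (int ky = 0; ky < k; ++ky)
      for (int kx = 0; kx < k; ++kx) {
        const int off = kx + k * (ky + k * kz);
        const int foff = (k - 1 - kx) + k * ((k - 1 - ky) + k * (k - 1 - kz));
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co)
            Wf(ci, co + Cout * off) =
              (float)W[co + (R_xlen_t)Cout * (ci + Cin * foff)];
      }
  arma::fvec dXf((R_xlen_t)Cin * N);
  conv3_run(dYf.memptr(), Cout, d1, d2, d3, Wf, k, nullptr, dXf.memptr());
  NumericVector dX((R_xlen_t)Cin * N);
  for (R_xlen_t i = 0; i < dX.size(); ++i) dX[i] = dXf[i];
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(rng = false)]]
List c_maxpool_fw(NumericVector X, IntegerVector xdim) {
  const int C = xdim[0], d1 = xdim[1], d2 = xdim[2], d3 = xdim[3];
  if (d1 % 2 || d2 % 2 || d3 % 2) stop("max-pool needs even extents");
  const int o1 = d1 / 2, o2 = d2 / 2, o3 = d3 / 2;
  NumericVector Y((R_xlen_t)C * o1 * o2 * o3);
  IntegerVector idx(Y.size());
  const double* x = X.begin();
  R_xlen_t o = 0;
  for (int z = 0; z < o3; ++z)
    for (int y = 0; y < o2; ++y)
      for (int xx = 0; xx < o1; ++xx)
        for (int c = 0; c < C; ++c, ++o) {
          double best = -HUGE_VAL; R_xlen_t bi = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                R_xlen_t i = (R_xlen_t)c +
                  (R_xlen_t)C * vox3(2 * xx + dx, 2 * y + dy, 2 * z + dz, d1, d2);
                if (x[i] > best) { best = x[i]; bi = i; }
              }
          Y[o] = best; idx[o] = (int)bi;
        }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export(rng = false)]]
NumericVector c_maxpool_bw(NumericVector dY, IntegerVector idx, R_xlen_t xlen) {
  NumericVector dX(xlen);
  for (R_xlen_t i = 0; i < dY.size(); ++i) dX[idx[i]] += dY[i];
  return dX;
}

// [[Rcpp::export(rng = false)]]
NumericVector c_upsample_fw(NumericVector X, IntegerVector xdim) {
  const int C = xdim[0], d1 = xdim[1], d2 = xdim[2], d3 = xdim[3];
  const int o1 = 2 * d1, o2 = 2 * d2, o3 = 2 * d3;
  NumericVector Y((R_xlen_t)C * o1 * o2 * o3);
  for (int z = 0; z < o3; ++z)
    for (int y = 0; y < o2; ++y)
      for (int x = 0; x < o1; ++x) {
        const double* s = X.begin() + (R_xlen_t)C * vox3(x / 2, y / 2, z / 2, d1, d2);
        double* t = Y.begin() + (R_xlen_t)C * vox3(x, y, z, o1, o2);
        for (int c = 0; c < C; ++c) t[c] = s[c];
      }
  return Y;
}

// [[Rcpp::export(rng = false)]]
NumericVector c_upsample_bw(NumericVector dY, IntegerVector ydim) {
  const int C = ydim[0], o1 = ydim[1], o2 = ydim[2], o3 = ydim[3];
  const int d1 = o1 / 2, d2 = o2 / 2, d3 = o3 / 2;
  NumericVector dX((R_xlen_t)C * d1 * d2 * d3);
  for (int z = 0; z < o3; ++z)
    for (int y = 0; y < o2; ++y)
      for (int x = 0; x < o1; ++x) {
        const double* s = dY.begin() + (R_xlen_t)C * vox3(x, y, z, o1, o2);
        double* t = dX.begin() + (R_xlen_t)C * vox3(x / 2, y / 2, z / 2, d1, d2);
        for (int c = 0; c < C; ++c) t[c] += s[c];
      }
  return dX;
}

// oob: 0 = zero outside, 1 = clamp to border
static inline double fetch(const double* v, int x, int y, int z,
                           int d1, int d2, int d3, int oob) {
  if (x < 0 || x >= d1 || y < 0 || y >= d2 || z < 0 || z >= d3) {
    if (oob == 0) return 0.0;
    x = std::min(std::max(x, 0), d1 - 1);
    y = std::min(std::max(y, 0), d2 - 1);
    z = std::min(std::max(z, 0), d3 - 1);
  }
  return v[vox3(x, y, z, d1, d2)];
}

static inline double lerp1(double a, double b, double t) {
  return a + t * (b - a);   // exact for a == b and for t == 0
}

static inline double sample_tri(const double* v, double cx, double cy, double cz,
                                int d1, int d2, int d3, int oob) {
  const int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
  const double fx = cx - x0, fy = cy - y0, fz = cz - z0;
  double c[2][2];
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      c[dy][dz] = lerp1(fetch(v, x0, y0 + dy, z0 + dz, d1, d2, d3, oob),
                        fetch(v, x0 + 1, y0 + dy, z0 + dz, d1, d2, d3, oob),
                        fx);
  return lerp1(lerp1(c[0][0], c[1][0], fy), lerp1(c[0][1], c[1][1], fy), fz);
}

// interp: 0 = nearest, 1 = trilinear
// [[Rcpp::export(rng = false)]]
NumericVector c_warp(NumericVector src, IntegerVector sdim,
                     NumericVector dvf, IntegerVector odim,
                     int interp, int oob) {
  const int s1 = sdim[0], s2 = sdim[1], s3 = sdim[2];
  const int o1 = odim[0], o2 = odim[1], o3 = odim[2];
  const R_xlen_t n = (R_xlen_t)o1 * o2 * o3;
  NumericVector Y(n);
  const double* u1 = dvf.begin();
  const double* u2 = u1 + n;
  const double* u3 = u2 + n;
  const double* v = src.begin();
  R_xlen_t i = 0;
  for (int z = 0; z < o3; ++z)
    for (int y = 0; y < o2; ++y)
      for (int x = 0; x < o1; ++x, ++i) {
        const double cx = x + u1[i], cy = y + u2[i], cz = z + u3[i];
        if (interp == 0) {
          Y[i] = fetch(v, (int)std::lround(cx), (int)std::lround(cy),
                       (int)std::lround(cz), s1, s2, s3, oob);
        } else {
          Y[i] = sample_tri(v, cx, cy, cz, s1, s2, s3, oob);
        }
      }
  return Y;
}

// Gradient of a trilinear zero-extension warp with respect to the displacement
// field. Returns dL/du as an (o1,o2,o3,3) array given dL/dOut.
// [[Rcpp::export(rng = false)]]
NumericVector c_warp_bw(NumericVector src, IntegerVector sdim,
                        NumericVector dvf, IntegerVector odim,
                        NumericVector dOut) {
  const int s1 = sdim[0], s2 = sdim[1], s3 = sdim[2];
  const int o1 = odim[0], o2 = odim[1], o3 = odim[2];
  const R_xlen_t n = (R_xlen_t)o1 * o2 * o3;
  NumericVector dU(3 * n);
  const double* u1 = dvf.begin();
  const double* u2 = u1 + n;
  const double* u3 = u2 + n;
  const double* v = src.begin();
  R_xlen_t i = 0;
  for (int z = 0; z < o3; ++z)
    for (int y = 0; y < o2; ++y)
      for (int x = 0; x < o1; ++x, ++i) {
        const double g = dOut[i];
        if (g == 0.0) continue;
        const double cx = x + u1[i], cy = y + u2[i], cz = z + u3[i];
        const int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy),
                  z0 = (int)std::floor(cz);
        const double fx = cx - x0, fy = cy - y0, fz = cz - z0;
        double c[2][2][2];
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx)
              c[dx][dy][dz] = fetch(v, x0 + dx, y0 + dy, z0 + dz, s1, s2, s3, 0);
        double gx = 0, gy = 0, gz = 0;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy) {
            const double wyz = (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
            gx += (c[1][dy][dz] - c[0][dy][dz]) * wyz;
          }
        for (int dz = 0; dz < 2; ++dz)
          for (int dx = 0; dx < 2; ++dx) {
            const double wxz = (dx ? fx : 1 - fx) * (dz ? fz : 1 - fz);
            gy += (c[dx][1][dz] - c[dx][0][dz]) * wxz;
          }
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            const double wxy = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy);
            gz += (c[dx][dy][1] - c[dx][dy][0]) * wxy;
          }
        dU[i] = g * gx;
        dU[i + n] = g * gy;
        dU[i + 2 * n] = g * gz;
      }
  return dU;
}

// [[Rcpp::export(rng = false)]]
NumericVector c_sample_points(NumericVector src, IntegerVector sdim,
                              NumericMatrix pts, int interp, int oob) {
  const int s1 = sdim[0], s2 = sdim[1], s3 = sdim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double* v = src.begin();
  for (int i = 0; i < n; ++i) {
    const double cx = pts(i, 0), cy = pts(i, 1), cz = pts(i, 2);
    if (interp == 0)
      out[i] = fetch(v, (int)std::lround(cx), (int)std::lround(cy),
                     (int)std::lround(cz), s1, s2, s3, oob);
    else
      out[i] = sample_tri(v, cx, cy, cz, s1, s2, s3, oob);
  }
  return out;
}

// Separable 1-D convolution along one axis of a 3-D array, zero extension.
// taps has odd length; taps[h] is the centre.
// [[Rcpp::export(rng = false)]]
NumericVector c_sepconv1(NumericVector X, IntegerVector dims,
                         NumericVector taps, int axis) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int nt = taps.size(), h = (nt - 1) / 2;
  NumericVector Y((R_xlen_t)d1 * d2 * d3);
  const double* x = X.begin();
  double* y = Y.begin();
  const int ext[3] = {d1, d2, d3};
  const R_xlen_t stride[3] = {1, (R_xlen_t)d1, (R_xlen_t)d1 * d2};
  const int n = ext[axis];
  const R_xlen_t st = stride[axis];
  for (int z = 0; z < d3; ++z)
    for (int yy = 0; yy < d2; ++yy)
      for (int xx = 0; xx < d1; ++xx) {
        const int pos[3] = {xx, yy, z};
        const int p = pos[axis];
        const R_xlen_t base = vox3(xx, yy, z, d1, d2);
        double acc = 0.0;
        const int t0 = std::max(0, h - p), t1 = std::min(nt, n - p + h);
        const double* xc = x + base - (R_xlen_t)(p)*st;
        for (int t = t0; t < t1; ++t) acc += taps[t] * xc[(R_xlen_t)(p + t - h) * st];
        y[base] = acc;
      }
  return Y;
}

// Channel-first concatenation / split along dimension 1.
// [[Rcpp::export(rng = false)]]
NumericVector c_concat_c(List parts, IntegerVector chans, R_xlen_t nvox) {
  const int np = parts.size();
  int ctot = 0;
  for (int p = 0; p < np; ++p) ctot += chans[p];
  NumericVector out((R_xlen_t)ctot * nvox);
  double* o = out.begin();
  std::vector<const double*> src(np);
  for (int p = 0; p < np; ++p) src[p] = REAL((SEXP)parts[p]);
  for (R_xlen_t v = 0; v < nvox; ++v) {
    double* dst = o + (R_xlen_t)ctot * v;
    for (int p = 0; p < np; ++p) {
      std::memcpy(dst, src[p] + (R_xlen_t)chans[p] * v,
                  sizeof(double) * chans[p]);
      dst += chans[p];
    }
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List c_split_c(NumericVector g, IntegerVector chans, R_xlen_t nvox) {
  const int np = chans.size();
  int ctot = 0;
  for (int p = 0; p < np; ++p) ctot += chans[p];
  List out(np);
  std::vector<double*> dst(np);
  for (int p = 0; p < np; ++p) {
    NumericVector part((R_xlen_t)chans[p] * nvox);
    out[p] = part;
    dst[p] = part.begin();
  }
  const double* s = g.begin();
  for (R_xlen_t v = 0; v < nvox; ++v) {
    const double* sp = s + (R_xlen_t)ctot * v;
    for (int p = 0; p < np; ++p) {
      std::memcpy(dst[p] + (R_xlen_t)chans[p] * v, sp,
                  sizeof(double) * chans[p]);
      sp += chans[p];
    }
  }
  return out;
}
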