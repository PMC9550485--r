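// Low-level tensor kernels: 3D convolution (im2col + BLAS), trilinear
// resizing and warping with adjoints, nearest-neighbour label warping,
// border-clipped box sums, and separable 1D smoothing.
//
// Array conventions (match R's column-major storage):
//   feature maps  : dim (X, Y, Z, C), spatial index fastest
//   displacement  : dim (X, Y, Z, 3), components x,y,z in voxel units
//   conv weights  : dim (k, k, k, C_in, C_out) flattened to a
//                   (k^3*C_in) x C_out matrix column-by-column

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_extent(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// First/last output index whose input sample o*stride - pad + koff lies in
// [0, n); gives branch-free interiors in the im2col/col2im loops.
static inline void valid_range(int n_out, int n_in, int stride, int pad,
                               int koff, int& lo, int& hi) {
  // smallest o with o*stride >= pad - koff
  int a = pad - koff;
  lo = a <= 0 ? 0 : (a + stride - 1) / stride;
  // largest o with o*stride <= n_in - 1 + pad - koff
  int b = n_in - 1 + pad - koff;
  hi = b < 0 ? -1 : b / stride;
  if (hi > n_out - 1) hi = n_out - 1;
}

// Fill the im2col matrix: rows = output voxels, cols = k^3 * C_in patch
// entries, zero where the receptive field leaves the (zero-padded) domain.
static void im2col(const double* x, int X, int Y, int Z, int Cin,
                   int k, int stride, int pad, arma::mat& col) {
  const int OX = out_extent(X, k, stride, pad);
  const int OY = out_extent(Y, k, stride, pad);
  const int OZ = out_extent(Z, k, stride, pad);
  const int k3 = k * k * k;
  const long XY = (long)X * Y;
  col.zeros();
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (long)ci * XY * Z;
    for (int kz = 0; kz < k; ++kz) {
      int zlo, zhi; valid_range(OZ, Z, stride, pad, kz, zlo, zhi);
      for (int ky = 0; ky < k; ++ky) {
        int ylo, yhi; valid_range(OY, Y, stride, pad, ky, ylo, yhi);
        for (int kx = 0; kx < k; ++kx) {
          int xlo, xhi; valid_range(OX, X, stride, pad, kx, xlo, xhi);
          const int j = kx + k * (ky + k * kz) + k3 * ci;
          double* colj = col.colptr(j);
          for (int oz = zlo; oz <= zhi; ++oz) {
            const long zoff = XY * (oz * stride - pad + kz);
            for (int oy = ylo; oy <= yhi; ++oy) {
              const double* src = xc + zoff + (long)X * (oy * stride - pad + ky)
                                  - pad + kx;
              double* dst = colj + ((long)oz * OY + oy) * OX;
              if (stride == 1) {
                std::copy(src + xlo, src + xhi + 1, dst + xlo);
              } else {
                for (int ox = xlo; ox <= xhi; ++ox) dst[ox] = src[ox * stride];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_conv3d_forward(NumericVector x, IntegerVector xdim,
                        NumericMatrix Wt, NumericVector b,
                        int k, int stride, int pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int OX = out_extent(X, k, stride, pad);
  const int OY = out_extent(Y, k, stride, pad);
  const int OZ = out_extent(Z, k, stride, pad);
  const int Cout = Wt.ncol();
  const long Nout = (long)OX * OY * OZ;

  arma::mat col(Nout, (long)k * k * k * Cin);
  im2col(x.begin(), X, Y, Z, Cin, k, stride, pad, col);
  const arma::mat W(const_cast<double*>(Wt.begin()), Wt.nrow(), Cout, false, true);
  arma::mat y = col * W;
  for (int co = 0; co < Cout; ++co) y.col(co) += b[co];

  NumericVector out(y.memptr(), y.memptr() + y.n_elem);
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, Cout);
  return List::create(_["y"] = out);
}

// [[Rcpp::export]]
List cpp_conv3d_backward(NumericVector x, IntegerVector xdim,
                         NumericMatrix Wt, int k, int stride, int pad,
                         NumericVector gy, IntegerVector ydim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int OX = ydim[0], OY = ydim[1], OZ = ydim[2], Cout = ydim[3];
  const long Nout = (long)OX * OY * OZ;
  const int k3 = k * k * k;

  arma::mat col(Nout, (long)k3 * Cin);
  im2col(x.begin(), X, Y, Z, Cin, k, stride, pad, col);
  const arma::mat W(const_cast<double*>(Wt.begin()), Wt.nrow(), Cout, false, true);
  const arma::mat gym(const_cast<double*>(gy.begin()), Nout, Cout, false, true);

  arma::mat gW = col.t() * gym;          // (k3*Cin) x Cout
  arma::rowvec gb = arma::sum(gym, 0);
  col.reset();
  arma::mat gcol = gym * W.t();          // Nout x (k3*Cin)

  // col2im: scatter-add patch gradients back onto the input grid
  NumericVector gx((long)X * Y * Z * Cin);
  const long XY = (long)X * Y;
  for (int ci = 0; ci < Cin; ++ci) {
    double* gxc = gx.begin() + (long)ci * XY * Z;
    for (int kz = 0; kz < k; ++kz) {
      int zlo, zhi; valid_range(OZ, Z, stride, pad, kz, zlo, zhi);
      for (int ky = 0; ky < k; ++ky) {
        int ylo, yhi; valid_range(OY, Y, stride, pad, ky, ylo, yhi);
        for (int kx = 0; kx < k; ++kx) {
          int xlo, xhi; valid_range(OX, X, stride, pad, kx, xlo, xhi);
          const int j = kx + k * (ky + k * kz) + k3 * ci;
          const double* gcj = gcol.colptr(j);
          for (int oz = zlo; oz <= zhi; ++oz) {
            const long zoff = XY * (oz * stride - pad + kz);
            for (int oy = ylo; oy <= yhi; ++oy) {
              double* dst = gxc + zoff + (long)X * (oy * stride - pad + ky)
                            - pad + kx;
              const double* src = gcj + ((long)oz * OY + oy) * OX;
              if (stride == 1) {
                for (int ox = xlo; ox <= xhi; ++ox) dst[ox] += src[ox];
              } else {
                for (int ox = xlo; ox <= xhi; ++ox) dst[ox * stride] += src[ox];
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  NumericVector gWv(gW.memptr(), gW.memptr() + gW.n_elem);
  gWv.attr("dim") = IntegerVector::create(Wt.nrow(), Cout);
  return List::create(_["gx"] = gx, _["gW"] = gWv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// Trilinear resize with half-voxel alignment: src = (o + .5) * in/out - .5,
// clamped to the domain.  Used for decoder upsampling (factors 2/4/8).
// [[Rcpp::export]]
NumericVector cpp_resize_trilinear(NumericVector x, IntegerVector xdim,
                                   IntegerVector odim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int OX = odim[0], OY = odim[1], OZ = odim[2];
  const double sx = (double)X / OX, sy = (double)Y / OY, sz = (double)Z / OZ;
  const long XY = (long)X * Y, Nin = XY * Z;
  NumericVector out((long)OX * OY * OZ * C);
  std::vector<int> x0v(OX), x1v(OX), y0v(OY), y1v(OY), z0v(OZ), z1v(OZ);
  std::vector<double> fxv(OX), fyv(OY), fzv(OZ);
  for (int o = 0; o < OX; ++o) {
    double p = std::min(std::max((o + 0.5) * sx - 0.5, 0.0), (double)(X - 1));
    x0v[o] = (int)p; x1v[o] = std::min(x0v[o] + 1, X - 1); fxv[o] = p - x0v[o];
  }
  for (int o = 0; o < OY; ++o) {
    double p = std::min(std::max((o + 0.5) * sy - 0.5, 0.0), (double)(Y - 1));
    y0v[o] = (int)p; y1v[o] = std::min(y0v[o] + 1, Y - 1); fyv[o] = p - y0v[o];
  }
  for (int o = 0; o < OZ; ++o) {
    double p = std::min(std::max((o + 0.5) * sz - 0.5, 0.0), (double)(Z - 1));
    z0v[o] = (int)p; z1v[o] = std::min(z0v[o] + 1, Z - 1); fzv[o] = p - z0v[o];
  }
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (long)c * Nin;
    double* oc = out.begin() + (long)c * OX * OY * OZ;
    long r = 0;
    for (int oz = 0; oz < OZ; ++oz)
      for (int oy = 0; oy < OY; ++oy)
        for (int ox = 0; ox < OX; ++ox, ++r) {
          const double fx = fxv[ox], fy = fyv[oy], fz = fzv[oz];
          const long i000 = x0v[ox] + (long)X * y0v[oy] + XY * z0v[oz];
          const long i100 = x1v[ox] + (long)X * y0v[oy] + XY * z0v[oz];
          const long i010 = x0v[ox] + (long)X * y1v[oy] + XY * z0v[oz];
          const long i110 = x1v[ox] + (long)X * y1v[oy] + XY * z0v[oz];
          const long i001 = x0v[ox] + (long)X * y0v[oy] + XY * z1v[oz];
          const long i101 = x1v[ox] + (long)X * y0v[oy] + XY * z1v[oz];
          const long i011 = x0v[ox] + (long)X * y1v[oy] + XY * z1v[oz];
          const long i111 = x1v[ox] + (long)X * y1v[oy] + XY * z1v[oz];
          oc[r] =
            (1 - fz) * ((1 - fy) * ((1 - fx) * xc[i000] + fx * xc[i100]) +
                        fy * ((1 - fx) * xc[i010] + fx * xc[i110])) +
            fz * ((1 - fy) * ((1 - fx) * xc[i001] + fx * xc[i101]) +
                  fy * ((1 - fx) * xc[i011] + fx * xc[i111]));
        }
  }
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, C);
  return out;
}

// Adjoint of cpp_resize_trilinear: scatter output gradients back.
// [[Rcpp::export]]
NumericVector cpp_resize_trilinear_backward(NumericVector gy, IntegerVector odim,
                                            IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int OX = odim[0], OY = odim[1], OZ = odim[2];
  const double sx = (double)X / OX, sy = (double)Y / OY, sz = (double)Z / OZ;
  const long XY = (long)X * Y, Nin = XY * Z;
  NumericVector gx(Nin * C);
  for (int c = 0; c < C; ++c) {
    const double* gc = gy.begin() + (long)c * OX * OY * OZ;
    double* xc = gx.begin() + (long)c * Nin;
    long r = 0;
    for (int oz = 0; oz < OZ; ++oz) {
      double pz = std::min(std::max((oz + 0.5) * sz - 0.5, 0.0), (double)(Z - 1));
      int z0 = (int)pz, z1 = std::min(z0 + 1, Z - 1); double fz = pz - z0;
      for (int oy = 0; oy < OY; ++oy) {
        double py = std::min(std::max((oy + 0.5) * sy - 0.5, 0.0), (double)(Y - 1));
        int y0 = (int)py, y1 = std::min(y0 + 1, Y - 1); double fy = py - y0;
        for (int ox = 0; ox < OX; ++ox, ++r) {
          double px = std::min(std::max((ox + 0.5) * sx - 0.5, 0.0), (double)(X - 1));
          int x0 = (int)px, x1 = std::min(x0 + 1, X - 1); double fx = px - x0;
          const double g = gc[r];
          xc[x0 + (long)X * y0 + XY * z0] += g * (1 - fx) * (1 - fy) * (1 - fz);
          xc[x1 + (long)X * y0 + XY * z0] += g * fx * (1 - fy) * (1 - fz);
          xc[x0 + (long)X * y1 + XY * z0] += g * (1 - fx) * fy * (1 - fz);
          xc[x1 + (long)X * y1 + XY * z0] += g * fx * fy * (1 - fz);
          xc[x0 + (long)X * y0 + XY * z1] += g * (1 - fx) * (1 - fy) * fz;
          xc[x1 + (long)X * y0 + XY * z1] += g * fx * (1 - fy) * fz;
          xc[x0 + (long)X * y1 + XY * z1] += g * (1 - fx) * fy * fz;
          xc[x1 + (long)X * y1 + XY * z1] += g * fx * fy * fz;
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  return gx;
}

// Trilinear warp: out(i) = m(i + u(i)), 8-corner interpolation with weights
// prod_d (1 - |j_d - p_d|).  boundary: 0 = clamp-to-border, 1 = zeros.
// [[Rcpp::export]]
NumericVector cpp_warp_trilinear(NumericVector m, IntegerVector dim,
                                 NumericVector u, int boundary) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  const long XY = (long)X * Y, N = XY * Z;
  const double *ux = u.begin(), *uy = u.begin() + N, *uz = u.begin() + 2 * N;
  NumericVector out(N);
  long i = 0;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x, ++i) {
        double px = x + ux[i], py = y + uy[i], pz = z + uz[i];
        if (boundary == 0) {
          px = std::min(std::max(px, 0.0), (double)(X - 1));
          py = std::min(std::max(py, 0.0), (double)(Y - 1));
          pz = std::min(std::max(pz, 0.0), (double)(Z - 1));
          int x0 = (int)px, y0 = (int)py, z0 = (int)pz;
          int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1),
              z1 = std::min(z0 + 1, Z - 1);
          double fx = px - x0, fy = py - y0, fz = pz - z0;
          out[i] =
            (1 - fz) * ((1 - fy) * ((1 - fx) * m[x0 + (long)X * y0 + XY * z0] +
                                    fx * m[x1 + (long)X * y0 + XY * z0]) +
                        fy * ((1 - fx) * m[x0 + (long)X * y1 + XY * z0] +
                              fx * m[x1 + (long)X * y1 + XY * z0])) +
            fz * ((1 - fy) * ((1 - fx) * m[x0 + (long)X * y0 + XY * z1] +
                              fx * m[x1 + (long)X * y0 + XY * z1]) +
                  fy * ((1 - fx) * m[x0 + (long)X * y1 + XY * z1] +
                        fx * m[x1 + (long)X * y1 + XY * z1]));
        } else {
          const int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
                    z0 = (int)std::floor(pz);
          const double fx = px - x0, fy = py - y0, fz = pz - z0;
          double acc = 0.0;
          for (int c = 0; c < 8; ++c) {
            const int xx = x0 + (c & 1), yy = y0 + ((c >> 1) & 1), zz = z0 + (c >> 2);
            if (xx < 0 || xx >= X || yy < 0 || yy >= Y || zz < 0 || zz >= Z) continue;
            const double w = ((c & 1) ? fx : 1 - fx) * (((c >> 1) & 1) ? fy : 1 - fy) *
                             ((c >> 2) ? fz : 1 - fz);
            acc += w * m[xx + (long)X * yy + XY * zz];
          }
          out[i] = acc;
        }
      }
  out.attr("dim") = IntegerVector::create(X, Y, Z);
  return out;
}

// Gradients of the trilinear warp w.r.t. the moving image (scatter of the
// corner weights) and the displacement field (image-gradient chain rule,
// zero where a clamped coordinate saturates the border).
// [[Rcpp::export]]
List cpp_warp_trilinear_backward(NumericVector m, IntegerVector dim,
                                 NumericVector u, NumericVector gy,
                                 int boundary) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  const long XY = (long)X * Y, N = XY * Z;
  const double *ux = u.begin(), *uy = u.begin() + N, *uz = u.begin() + 2 * N;
  NumericVector gm(N), gu(3 * N);
  double *gux = gu.begin(), *guy = gu.begin() + N, *guz = gu.begin() + 2 * N;
  long i = 0;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x, ++i) {
        const double g = gy[i];
        double px = x + ux[i], py = y + uy[i], pz = z + uz[i];
        bool cx = false, cy = false, cz = false;  // clamped => zero gradient
        int x0, y0, z0;
        if (boundary == 0) {
          if (px <= 0.0) { px = 0.0; cx = true; }
          if (px >= X - 1) { px = X - 1; cx = true; }
          if (py <= 0.0) { py = 0.0; cy = true; }
          if (py >= Y - 1) { py = Y - 1; cy = true; }
          if (pz <= 0.0) { pz = 0.0; cz = true; }
          if (pz >= Z - 1) { pz = Z - 1; cz = true; }
          x0 = (int)px; y0 = (int)py; z0 = (int)pz;
        } else {
          x0 = (int)std::floor(px); y0 = (int)std::floor(py); z0 = (int)std::floor(pz);
        }
        const double fx = px - x0, fy = py - y0, fz = pz - z0;
        double ddx = 0, ddy = 0, ddz = 0;
        for (int c = 0; c < 8; ++c) {
          int xx = x0 + (c & 1), yy = y0 + ((c >> 1) & 1), zz = z0 + (c >> 2);
          if (boundary == 0) {
            xx = std::min(xx, X - 1); yy = std::min(yy, Y - 1); zz = std::min(zz, Z - 1);
          } else if (xx < 0 || xx >= X || yy < 0 || yy >= Y || zz < 0 || zz >= Z) {
            continue;
          }
          const double wx = (c & 1) ? fx : 1 - fx;
          const double wy = ((c >> 1) & 1) ? fy : 1 - fy;
          const double wz = (c >> 2) ? fz : 1 - fz;
          const long j = xx + (long)X * yy + XY * zz;
          gm[j] += g * wx * wy * wz;
          const double mv = m[j];
          ddx += mv * ((c & 1) ? 1.0 : -1.0) * wy * wz;
          ddy += mv * (((c >> 1) & 1) ? 1.0 : -1.0) * wx * wz;
          ddz += mv * ((c >> 2) ? 1.0 : -1.0) * wx * wy;
        }
        gux[i] = cx ? 0.0 : g * ddx;
        guy[i] = cy ? 0.0 : g * ddy;
        guz[i] = cz ? 0.0 : g * ddz;
      }
  gm.attr("dim") = dim;
  gu.attr("dim") = IntegerVector::create(X, Y, Z, 3);
  return List::create(_["gm"] = gm, _["gu"] = gu);
}

// Nearest-neighbour warp for integer label maps (labels stay integral).
// [[Rcpp::export]]
IntegerVector cpp_warp_nn(IntegerVector l, IntegerVector dim, NumericVector u,
                          int boundary) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  const long XY = (long)X * Y, N = XY * Z;
  const double *ux = u.begin(), *uy = u.begin() + N, *uz = u.begin() + 2 * N;
  IntegerVector out(N);
  long i = 0;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x, ++i) {
        int xx = (int)std::lround(x + ux[i]);
        int yy = (int)std::lround(y + uy[i]);
        int zz = (int)std::lround(z + uz[i]);
        if (boundary == 0) {
          xx = std::min(std::max(xx, 0), X - 1);
          yy = std::min(std::max(yy, 0), Y - 1);
          zz = std::min(std::max(zz, 0), Z - 1);
          out[i] = l[xx + (long)X * yy + XY * zz];
        } else {
          out[i] = (xx < 0 || xx >= X || yy < 0 || yy >= Y || zz < 0 || zz >= Z)
                     ? 0 : l[xx + (long)X * yy + XY * zz];
        }
      }
  out.attr("dim") = dim;
  return out;
}

// Sliding cubic-window sums with border clipping, separable per axis.
// Window along each axis is [i - r, i + r] intersected with the domain.
// [[Rcpp::export]]
NumericVector cpp_boxsum3d(NumericVector x, IntegerVector dim, int r) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  const long XY = (long)X * Y, N = XY * Z;
  std::vector<double> a(x.begin(), x.end()), tmp(N);
  // pass along x
  for (long line = 0; line < N / X; ++line) {
    const double* in = a.data() + line * X;
    double* outp = tmp.data() + line * X;
    double s = 0; int hi = std::min(r, X - 1);
    for (int i = 0; i <= hi; ++i) s += in[i];
    outp[0] = s;
    for (int i = 1; i < X; ++i) {
      if (i + r < X) s += in[i + r];
      if (i - r - 1 >= 0) s -= in[i - r - 1];
      outp[i] = s;
    }
  }
  // pass along y (stride X within each z-slab)
  for (int z = 0; z < Z; ++z)
    for (int xi = 0; xi < X; ++xi) {
      double* base = tmp.data() + XY * z + xi;
      double* outp = a.data() + XY * z + xi;
      double s = 0; int hi = std::min(r, Y - 1);
      for (int i = 0; i <= hi; ++i) s += base[(long)X * i];
      outp[0] = s;
      for (int i = 1; i < Y; ++i) {
        if (i + r < Y) s += base[(long)X * (i + r)];
        if (i - r - 1 >= 0) s -= base[(long)X * (i - r - 1)];
        outp[(long)X * i] = s;
      }
    }
  // pass along z (stride XY)
  for (long xy = 0; xy < XY; ++xy) {
    double* base = a.data() + xy;
    double* outp = tmp.data() + xy;
    double s = 0; int hi = std::min(r, Z - 1);
    for (int i = 0; i <= hi; ++i) s += base[XY * i];
    outp[0] = s;
    for (int i = 1; i < Z; ++i) {
      if (i + r < Z) s += base[XY * (i + r)];
      if (i - r - 1 >= 0) s -= base[XY * (i - r - 1)];
      outp[XY * i] = s;
    }
  }
  NumericVector out(tmp.begin(), tmp.end());
  out.attr("dim") = dim;
  return out;
}

// Separable correlation with a symmetric 1D kernel, replicate padding.
// Used to impose a correlation length on white-noise displacement fields.
// [[Rcpp::export]]
NumericVector cpp_smooth_separable(NumericVector x, IntegerVector dim,
                                   NumericVector kernel) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  const long XY = (long)X * Y, N = XY * Z;
  const int kl = kernel.size(), r = (kl - 1) / 2;
  std::vector<double> a(x.begin(), x.end()), b(N);
  // x axis
  for (long line = 0; line < N / X; ++line) {
    const double* in = a.data() + line * X;
    double* outp = b.data() + line * X;
    for (int i = 0; i < X; ++i) {
      double s = 0;
      for (int t = -r; t <= r; ++t) {
        int j = std::min(std::max(i + t, 0), X - 1);
        s += kernel[t + r] * in[j];
      }
      outp[i] = s;
    }
  }
  // y axis
  for (int z = 0; z < Z; ++z)
    for (int xi = 0; xi < X; ++xi) {
      const double* in = b.data() + XY * z + xi;
      double* outp = a.data() + XY * z + xi;
      for (int i = 0; i < Y; ++i) {
        double s = 0;
        for (int t = -r; t <= r; ++t) {
          int j = std::min(std::max(i + t, 0), Y - 1);
          s += kernel[t + r] * in[(long)X * j];
        }
        outp[(long)X * i] = s;
      }
    }
  // z axis
  for (long xy = 0; xy < XY; ++xy) {
    const double* in = a.data() + xy;
    double* outp = b.data() + xy;
    for (int i = 0; i < Z; ++i) {
      double s = 0;
      for (int t = -r; t <= r; ++t) {
        int j = std::min(std::max(i + t, 0), Z - 1);
        s += kernel[t + r] * in[XY * j];
      }
      outp[XY * i] = s;
    }
  }
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = dim;
  return out;
}
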