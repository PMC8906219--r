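#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Trilinear / nearest-neighbour sampling of a 3D volume at continuous
// 0-based voxel coordinates.  mode: 0 = linear (outside -> bg),
// 1 = nearest (outside -> bg), 2 = linear with coordinates clamped into
// the domain (used for displacement-field resampling, where edge
// extension is the right boundary model).
// [[Rcpp::export]]
NumericVector cpp_interp3(NumericVector vox, IntegerVector dim,
                          NumericVector xi, NumericVector yi,
                          NumericVector zi, int mode, double bg) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = xi.size();
  NumericVector out(n);
  const double *v = vox.begin();
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = xi[p], y = yi[p], z = zi[p];
    if (mode == 2) {
      x = clampd(x, 0.0, nx - 1.0);
      y = clampd(y, 0.0, ny - 1.0);
      z = clampd(z, 0.0, nz - 1.0);
    }
    if (x < 0.0 || y < 0.0 || z < 0.0 ||
        x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
      out[p] = bg;
      continue;
    }
    if (mode == 1) {
      int i = (int)std::floor(x + 0.5), j = (int)std::floor(y + 0.5),
          k = (int)std::floor(z + 0.5);
      if (i > nx - 1) i = nx - 1;
      if (j > ny - 1) j = ny - 1;
      if (k > nz - 1) k = nz - 1;
      out[p] = v[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
    } else {
      int i0 = nx == 1 ? 0 : (int)std::floor(x);
      int j0 = ny == 1 ? 0 : (int)std::floor(y);
      int k0 = nz == 1 ? 0 : (int)std::floor(z);
      if (i0 > nx - 2 && nx > 1) i0 = nx - 2;
      if (j0 > ny - 2 && ny > 1) j0 = ny - 2;
      if (k0 > nz - 2 && nz > 1) k0 = nz - 2;
      const double tx = nx == 1 ? 0.0 : x - i0;
      const double ty = ny == 1 ? 0.0 : y - j0;
      const double tz = nz == 1 ? 0.0 : z - k0;
      const int i1 = nx == 1 ? 0 : i0 + 1;
      const int j1 = ny == 1 ? 0 : j0 + 1;
      const int k1 = nz == 1 ? 0 : k0 + 1;
      #define V(i, j, k) v[(i) + (R_xlen_t)nx * ((j) + (R_xlen_t)ny * (k))]
      const double c00 = V(i0, j0, k0) * (1 - tx) + V(i1, j0, k0) * tx;
      const double c10 = V(i0, j1, k0) * (1 - tx) + V(i1, j1, k0) * tx;
      const double c01 = V(i0, j0, k1) * (1 - tx) + V(i1, j0, k1) * tx;
      const double c11 = V(i0, j1, k1) * (1 - tx) + V(i1, j1, k1) * tx;
      #undef V
      const double c0 = c00 * (1 - ty) + c10 * ty;
      const double c1 = c01 * (1 - ty) + c11 * ty;
      out[p] = c0 * (1 - tz) + c1 * tz;
    }
  }
  return out;
}

static void conv_axis(std::vector<double> &a, std::vector<double> &b,
                      int nx, int ny, int nz, int axis,
                      const std::vector<double> &ker) {
  const int r = ((int)ker.size() - 1) / 2;
  const int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const R_xlen_t stride = axis == 0 ? sx : (axis == 1 ? sy : sz);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int m = axis == 0 ? i : (axis == 1 ? j : k);
        const R_xlen_t idx = i + sy * j + sz * k;
        double s = 0.0, wsum = 0.0;
        const int lo = m - r < 0 ? -m : -r;
        const int hi = m + r > len - 1 ? len - 1 - m : r;
        for (int o = lo; o <= hi; ++o) {
          const double w = ker[o + r];
          s += w * a[idx + stride * o];
          wsum += w;
        }
        b[idx] = s / wsum;  // boundary renormalization keeps constants fixed
      }
    }
  }
}

// Separable Gaussian smoothing; sigma given per axis in voxel units.
// Kernel discretely normalized (unit sum), truncated at 3 sigma, and
// renormalized where it overhangs the boundary.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vox, IntegerVector dim,
                         NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(vox.begin(), vox.end()), b(n);
  for (int axis = 0; axis < 3; ++axis) {
    const double s = sigma[axis];
    if (s < 1e-8) continue;
    const int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * r + 1);
    double ks = 0.0;
    for (int o = -r; o <= r; ++o) {
      ker[o + r] = std::exp(-0.5 * (o / s) * (o / s));
      ks += ker[o + r];
    }
    for (double &w : ker) w /= ks;
    conv_axis(a, b, nx, ny, nz, axis, ker);
    a.swap(b);
  }
  return NumericVector(a.begin(), a.end());
}

static inline void bspline_w(double t, double *w) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (3.0 * t3 - 6.0 * t2 + 4.0) / 6.0;
  w[2] = (-3.0 * t3 + 3.0 * t2 + 3.0 * t + 1.0) / 6.0;
  w[3] = t3 / 6.0;
}

// Evaluate a cubic B-spline FFD on a voxel grid.
// coef: (ncx, ncy, ncz, 3) column-major control displacements (mm).
// Returns (nx, ny, nz, 3) column-major displacement values (mm).
// [[Rcpp::export]]
NumericVector cpp_ffd_eval(NumericVector coef, IntegerVector ncp,
                           NumericVector cp_origin, NumericVector cp_spacing,
                           IntegerVector dim, NumericVector spacing,
                           NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int cx = ncp[0], cy = ncp[1], cz = ncp[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t nc = (R_xlen_t)cx * cy * cz;
  NumericVector out(n * 3);
  std::vector<double> wx(4), wy(4), wz(4);
  for (int k = 0; k < nz; ++k) {
    const double gz = (origin[2] + k * spacing[2] - cp_origin[2]) / cp_spacing[2];
    int kz = (int)std::floor(gz);
    if (kz < 1) kz = 1;
    if (kz > cz - 3) kz = cz - 3;
    bspline_w(gz - kz, wz.data());
    for (int j = 0; j < ny; ++j) {
      const double gy = (origin[1] + j * spacing[1] - cp_origin[1]) / cp_spacing[1];
      int jy = (int)std::floor(gy);
      if (jy < 1) jy = 1;
      if (jy > cy - 3) jy = cy - 3;
      bspline_w(gy - jy, wy.data());
      for (int i = 0; i < nx; ++i) {
        const double gx = (origin[0] + i * spacing[0] - cp_origin[0]) / cp_spacing[0];
        int ix = (int)std::floor(gx);
        if (ix < 1) ix = 1;
        if (ix > cx - 3) ix = cx - 3;
        bspline_w(gx - ix, wx.data());
        double u0 = 0.0, u1 = 0.0, u2 = 0.0;
        for (int c = 0; c < 4; ++c) {
          for (int b = 0; b < 4; ++b) {
            const double wyz = wy[b] * wz[c];
            const R_xlen_t base =
                (R_xlen_t)(ix - 1) +
                (R_xlen_t)cx * ((jy - 1 + b) + (R_xlen_t)cy * (kz - 1 + c));
            for (int a = 0; a < 4; ++a) {
              const double w = wx[a] * wyz;
              const R_xlen_t ci = base + a;
              u0 += w * coef[ci];
              u1 += w * coef[ci + nc];
              u2 += w * coef[ci + 2 * nc];
            }
          }
        }
        const R_xlen_t vi = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        out[vi] = u0;
        out[vi + n] = u1;
        out[vi + 2 * n] = u2;
      }
    }
  }
  return out;
}

// Transpose of cpp_ffd_eval: aggregate a per-voxel force field into a
// per-control-point gradient with the same tensor-product weights.
// [[Rcpp::export]]
NumericVector cpp_ffd_scatter(NumericVector force, IntegerVector ncp,
                              NumericVector cp_origin, NumericVector cp_spacing,
                              IntegerVector dim, NumericVector spacing,
                              NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int cx = ncp[0], cy = ncp[1], cz = ncp[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t nc = (R_xlen_t)cx * cy * cz;
  NumericVector grad(nc * 3);
  std::vector<double> wx(4), wy(4), wz(4);
  for (int k = 0; k < nz; ++k) {
    const double gz = (origin[2] + k * spacing[2] - cp_origin[2]) / cp_spacing[2];
    int kz = (int)std::floor(gz);
    if (kz < 1) kz = 1;
    if (kz > cz - 3) kz = cz - 3;
    bspline_w(gz - kz, wz.data());
    for (int j = 0; j < ny; ++j) {
      const double gy = (origin[1] + j * spacing[1] - cp_origin[1]) / cp_spacing[1];
      int jy = (int)std::floor(gy);
      if (jy < 1) jy = 1;
      if (jy > cy - 3) jy = cy - 3;
      bspline_w(gy - jy, wy.data());
      for (int i = 0; i < nx; ++i) {
        const double gx = (origin[0] + i * spacing[0] - cp_origin[0]) / cp_spacing[0];
        int ix = (int)std::floor(gx);
        if (ix < 1) ix = 1;
        if (ix > cx - 3) ix = cx - 3;
        bspline_w(gx - ix, wx.data());
        const R_xlen_t vi = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        const double f0 = force[vi], f1 = force[vi + n], f2 = force[vi + 2 * n];
        for (int c = 0; c < 4; ++c) {
          for (int b = 0; b < 4; ++b) {
            const double wyz = wy[b] * wz[c];
            const R_xlen_t base =
                (R_xlen_t)(ix - 1) +
                (R_xlen_t)cx * ((jy - 1 + b) + (R_xlen_t)cy * (kz - 1 + c));
            for (int a = 0; a < 4; ++a) {
              const double w = wx[a] * wyz;
              const R_xlen_t ci = base + a;
              grad[ci] += w * f0;
              grad[ci + nc] += w * f1;
              grad[ci + 2 * nc] += w * f2;
            }
          }
        }
      }
    }
  }
  return grad;
}

// Parzen joint histogram in the Mattes style: tent (linear) kernel along
// the fixed-intensity axis, cubic B-spline kernel along the moving axis,
// so the histogram -- and MI -- is C^2 in the moving intensities and its
// derivative vanishes at kernel peaks (no spurious force on an already
// registered pair).  Samples are clamped into the stated ranges; kernel
// mass overhanging the first/last bin is accumulated there.
// Returns a bins x bins matrix, fixed along rows.
// [[Rcpp::export]]
NumericMatrix cpp_hist2_pv(NumericVector f, NumericVector m, int bins,
                           NumericVector rf, NumericVector rm) {
  NumericMatrix counts(bins, bins);
  const double bwf = (rf[1] - rf[0]) / bins, bwm = (rm[1] - rm[0]) / bins;
  const R_xlen_t n = f.size();
  double wm[4];
  for (R_xlen_t k = 0; k < n; ++k) {
    double cf = (clampd(f[k], rf[0], rf[1]) - rf[0]) / bwf - 0.5;
    double cm = (clampd(m[k], rm[0], rm[1]) - rm[0]) / bwm - 0.5;
    int i0 = (int)std::floor(cf);
    if (i0 < 0) i0 = 0;
    if (i0 > bins - 2) i0 = bins - 2;
    const double tf = clampd(cf - i0, 0.0, 1.0);
    const int j = (int)std::floor(cm);
    const double t = cm - j;
    const double t2 = t * t, t3 = t2 * t;
    wm[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
    wm[1] = (3.0 * t3 - 6.0 * t2 + 4.0) / 6.0;
    wm[2] = (-3.0 * t3 + 3.0 * t2 + 3.0 * t + 1.0) / 6.0;
    wm[3] = t3 / 6.0;
    for (int o = 0; o < 4; ++o) {
      int jj = j - 1 + o;
      if (jj < 0) jj = 0;
      if (jj > bins - 1) jj = bins - 1;
      counts(i0, jj) += (1 - tf) * wm[o];
      counts(i0 + 1, jj) += tf * wm[o];
    }
  }
  return counts;
}

// Directed Hausdorff distance between two point sets (rows = points, mm).
// [[Rcpp::export]]
double cpp_hausdorff_directed(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  double hmax2 = 0.0;
  for (int a = 0; a < na; ++a) {
    const double ax = A(a, 0), ay = A(a, 1), az = A(a, 2);
    double dmin2 = R_PosInf;
    for (int b = 0; b < nb; ++b) {
      const double dx = ax - B(b, 0), dy = ay - B(b, 1), dz = az - B(b, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < dmin2) {
        dmin2 = d2;
        if (dmin2 <= hmax2) break;  // cannot raise the running max
      }
    }
    if (dmin2 > hmax2) hmax2 = dmin2;
  }
  return std::sqrt(hmax2);
}

// Exhaustive integer-voxel translation search maximizing Pearson NCC over
// the overlap region.  Returns c(sx, sy, sz, ncc, degenerate_flag).
// [[Rcpp::export]]
NumericVector cpp_best_shift(NumericVector f, NumericVector m,
                             IntegerVector dim, int maxshift) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double best = -2.0;
  int bx = 0, by = 0, bz = 0;
  bool any_valid = false;
  for (int sz = -maxshift; sz <= maxshift; ++sz) {
    for (int sy = -maxshift; sy <= maxshift; ++sy) {
      for (int sx = -maxshift; sx <= maxshift; ++sx) {
        // translated moving: m'(i) = m(i - s); overlap where both defined
        const int ilo = std::max(0, sx), ihi = std::min(nx, nx + sx);
        const int jlo = std::max(0, sy), jhi = std::min(ny, ny + sy);
        const int klo = std::max(0, sz), khi = std::min(nz, nz + sz);
        double sf = 0, sm = 0, sff = 0, smm = 0, sfm = 0;
        R_xlen_t cnt = 0;
        for (int k = klo; k < khi; ++k) {
          for (int j = jlo; j < jhi; ++j) {
            R_xlen_t fi = ilo + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            R_xlen_t mi = (ilo - sx) +
                          (R_xlen_t)nx * ((j - sy) + (R_xlen_t)ny * (k - sz));
            for (int i = ilo; i < ihi; ++i, ++fi, ++mi) {
              const double a = f[fi], b = m[mi];
              sf += a; sm += b; sff += a * a; smm += b * b; sfm += a * b;
              ++cnt;
            }
          }
        }
        if (cnt < 2) continue;
        const double vf = sff - sf * sf / cnt, vm = smm - sm * sm / cnt;
        if (vf <= 1e-12 || vm <= 1e-12) continue;
        const double r = (sfm - sf * sm / cnt) / std::sqrt(vf * vm);
        any_valid = true;
        // prefer the smaller shift on ties so the aligned case returns 0
        const bool better =
            r > best + 1e-12 ||
            (r > best - 1e-12 &&
             sx * sx + sy * sy + sz * sz < bx * bx + by * by + bz * bz);
        if (better) {
          best = r;
          bx = sx; by = sy; bz = sz;
        }
      }
    }
  }
  return NumericVector::create((double)bx, (double)by, (double)bz, best,
                               any_valid ? 0.0 : 1.0);
}
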