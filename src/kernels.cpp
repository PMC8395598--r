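// Numerical kernels for B-spline velocity fields, resampling, distance
// transforms, Hessian-based vesselness and histogram similarity measures.
// All dense fields are column-major (R array layout); vector fields carry the
// component as the 4th dimension.  Displacements are stored in mm along the
// image axes; conversion to voxel units happens here via the grid spacing.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// cubic B-spline basis
// ---------------------------------------------------------------------------

static inline void bw0(double t, double *w) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}
static inline void bw1(double t, double *w) {
  const double t2 = t * t;
  w[0] = (-3.0 + 6.0 * t - 3.0 * t2) / 6.0;
  w[1] = (-12.0 * t + 9.0 * t2) / 6.0;
  w[2] = (3.0 + 6.0 * t - 9.0 * t2) / 6.0;
  w[3] = t2 / 2.0;
}
static inline void bw2(double t, double *w) {
  w[0] = 1.0 - t;
  w[1] = 3.0 * t - 2.0;
  w[2] = 1.0 - 3.0 * t;
  w[3] = t;
}

static void bspline_weights(double t, int deriv, double *w) {
  if (deriv == 0) bw0(t, w);
  else if (deriv == 1) bw1(t, w);
  else bw2(t, w);
}

// Per-axis lookup tables: for image sample i, base control index and 4 weights.
struct AxisTable {
  std::vector<int> base;
  std::vector<double> w; // 4 per sample
};

// positions x_i = (i - origin) / spacing in control-grid units
static AxisTable axis_table(int n, double origin, double spacing, int nctrl,
                            int deriv, double deriv_scale) {
  AxisTable tab;
  tab.base.resize(n);
  tab.w.resize(4 * (size_t)n);
  const double sc = std::pow(deriv_scale, deriv);
  for (int i = 0; i < n; ++i) {
    double x = (static_cast<double>(i) - origin) / spacing;
    int j = static_cast<int>(std::floor(x));
    double t = x - j;
    int b = j - 1;
    if (b < 0 || b + 3 > nctrl - 1)
      stop("control grid does not cover the image with sufficient margin");
    double ww[4];
    bspline_weights(t, deriv, ww);
    tab.base[i] = b;
    for (int k = 0; k < 4; ++k) tab.w[4 * (size_t)i + k] = ww[k] * sc;
  }
  return tab;
}

// ---------------------------------------------------------------------------
// dense evaluation of a B-spline coefficient grid (and derivatives)
// ---------------------------------------------------------------------------

// coef: ncx*ncy*ncz*ncomp; returns nx*ny*nz*ncomp
// origin/spacing are in image-sample units along each axis; deriv_scale is the
// factor converting one control-grid unit to the physical unit the derivative
// is taken against (1/control_spacing_mm for mm derivatives).
// Separable implementation: tensor contraction one axis at a time.
// [[Rcpp::export]]
NumericVector cpp_bspline_eval(NumericVector coef, IntegerVector cdim,
                               NumericVector origin, NumericVector spacing,
                               IntegerVector dim, IntegerVector deriv,
                               NumericVector deriv_scale) {
  const int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t ncv = (size_t)ncx * ncy * ncz;
  const int ncomp = coef.size() / ncv;
  AxisTable tx = axis_table(nx, origin[0], spacing[0], ncx, deriv[0], deriv_scale[0]);
  AxisTable ty = axis_table(ny, origin[1], spacing[1], ncy, deriv[1], deriv_scale[1]);
  AxisTable tz = axis_table(nz, origin[2], spacing[2], ncz, deriv[2], deriv_scale[2]);
  NumericVector out((size_t)nx * ny * nz * ncomp);
  const size_t nvox = (size_t)nx * ny * nz;
  // T1[a, b, z] then T2[a, y, z] then out[x, y, z], per component
  std::vector<double> T1((size_t)ncx * ncy * nz);
  std::vector<double> T2((size_t)ncx * ny * nz);
  for (int c = 0; c < ncomp; ++c) {
    const double *cf = coef.begin() + c * ncv;
    double *o = out.begin() + c * nvox;
    for (int z = 0; z < nz; ++z) {
      const int bz = tz.base[z];
      const double *wz = &tz.w[4 * (size_t)z];
      for (int b = 0; b < ncy; ++b) {
        const double *c0 = cf + ((size_t)(bz + 0) * ncy + b) * ncx;
        const double *c1 = cf + ((size_t)(bz + 1) * ncy + b) * ncx;
        const double *c2 = cf + ((size_t)(bz + 2) * ncy + b) * ncx;
        const double *c3 = cf + ((size_t)(bz + 3) * ncy + b) * ncx;
        double *t = &T1[((size_t)z * ncy + b) * ncx];
        for (int a = 0; a < ncx; ++a)
          t[a] = wz[0] * c0[a] + wz[1] * c1[a] + wz[2] * c2[a] + wz[3] * c3[a];
      }
    }
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const int by = ty.base[y];
        const double *wy = &ty.w[4 * (size_t)y];
        const double *t0 = &T1[((size_t)z * ncy + by + 0) * ncx];
        const double *t1 = &T1[((size_t)z * ncy + by + 1) * ncx];
        const double *t2 = &T1[((size_t)z * ncy + by + 2) * ncx];
        const double *t3 = &T1[((size_t)z * ncy + by + 3) * ncx];
        double *t = &T2[((size_t)z * ny + y) * ncx];
        for (int a = 0; a < ncx; ++a)
          t[a] = wy[0] * t0[a] + wy[1] * t1[a] + wy[2] * t2[a] + wy[3] * t3[a];
      }
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const double *t = &T2[((size_t)z * ny + y) * ncx];
        double *oo = o + ((size_t)z * ny + y) * nx;
        for (int x = 0; x < nx; ++x) {
          const int bx = tx.base[x];
          const double *wx = &tx.w[4 * (size_t)x];
          oo[x] = wx[0] * t[bx] + wx[1] * t[bx + 1] + wx[2] * t[bx + 2] +
                  wx[3] * t[bx + 3];
        }
      }
  }
  return out;
}

// transpose of cpp_bspline_eval: scatter a dense (possibly multi-component)
// field into control-grid bins with the same weights (separable passes in
// reverse order).
// [[Rcpp::export]]
NumericVector cpp_bspline_splat(NumericVector field, IntegerVector cdim,
                                NumericVector origin, NumericVector spacing,
                                IntegerVector dim, IntegerVector deriv,
                                NumericVector deriv_scale) {
  const int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t ncv = (size_t)ncx * ncy * ncz;
  const size_t nvox = (size_t)nx * ny * nz;
  const int ncomp = field.size() / nvox;
  AxisTable tx = axis_table(nx, origin[0], spacing[0], ncx, deriv[0], deriv_scale[0]);
  AxisTable ty = axis_table(ny, origin[1], spacing[1], ncy, deriv[1], deriv_scale[1]);
  AxisTable tz = axis_table(nz, origin[2], spacing[2], ncz, deriv[2], deriv_scale[2]);
  NumericVector out(ncv * ncomp);
  std::vector<double> T2((size_t)ncx * ny * nz);
  std::vector<double> T1((size_t)ncx * ncy * nz);
  for (int c = 0; c < ncomp; ++c) {
    const double *f = field.begin() + c * nvox;
    double *o = out.begin() + c * ncv;
    std::fill(T2.begin(), T2.end(), 0.0);
    std::fill(T1.begin(), T1.end(), 0.0);
    // x pass: T2[a, y, z] += wx * f[x, y, z]
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const double *ff = f + ((size_t)z * ny + y) * nx;
        double *t = &T2[((size_t)z * ny + y) * ncx];
        for (int x = 0; x < nx; ++x) {
          const double v = ff[x];
          if (v == 0.0) continue;
          const int bx = tx.base[x];
          const double *wx = &tx.w[4 * (size_t)x];
          t[bx] += wx[0] * v; t[bx + 1] += wx[1] * v;
          t[bx + 2] += wx[2] * v; t[bx + 3] += wx[3] * v;
        }
      }
    // y pass: T1[a, b, z] += wy * T2[a, y, z]
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const int by = ty.base[y];
        const double *wy = &ty.w[4 * (size_t)y];
        const double *t = &T2[((size_t)z * ny + y) * ncx];
        for (int k = 0; k < 4; ++k) {
          double *tt = &T1[((size_t)z * ncy + by + k) * ncx];
          const double w = wy[k];
          for (int a = 0; a < ncx; ++a) tt[a] += w * t[a];
        }
      }
    // z pass: out[a, b, cz] += wz * T1[a, b, z]
    for (int z = 0; z < nz; ++z) {
      const int bz = tz.base[z];
      const double *wz = &tz.w[4 * (size_t)z];
      for (int b = 0; b < ncy; ++b) {
        const double *t = &T1[((size_t)z * ncy + b) * ncx];
        for (int k = 0; k < 4; ++k) {
          double *oo = o + ((size_t)(bz + k) * ncy + b) * ncx;
          const double w = wz[k];
          for (int a = 0; a < ncx; ++a) oo[a] += w * t[a];
        }
      }
    }
  }
  return out;
}

// evaluate the spline (velocity, mm) at arbitrary continuous positions given
// in control-grid units; clamps to the valid support (constant extrapolation).
static void spline_at(const double *cf, int ncx, int ncy, int ncz, int ncomp,
                      double gx, double gy, double gz, double *vout) {
  const size_t ncv = (size_t)ncx * ncy * ncz;
  double lo = 1.0, hix = ncx - 3.0, hiy = ncy - 3.0, hiz = ncz - 3.0;
  gx = std::min(std::max(gx, lo), hix - 1e-9);
  gy = std::min(std::max(gy, lo), hiy - 1e-9);
  gz = std::min(std::max(gz, lo), hiz - 1e-9);
  int jx = (int)std::floor(gx), jy = (int)std::floor(gy), jz = (int)std::floor(gz);
  double wx[4], wy[4], wz[4];
  bw0(gx - jx, wx); bw0(gy - jy, wy); bw0(gz - jz, wz);
  for (int c = 0; c < ncomp; ++c) vout[c] = 0.0;
  for (int kz = 0; kz < 4; ++kz) {
    const size_t oz = (size_t)(jz - 1 + kz) * ncy;
    for (int ky = 0; ky < 4; ++ky) {
      const double wyz = wz[kz] * wy[ky];
      const size_t oy = (oz + (size_t)(jy - 1 + ky)) * ncx + (jx - 1);
      for (int kx = 0; kx < 4; ++kx) {
        const double w = wyz * wx[kx];
        for (int c = 0; c < ncomp; ++c)
          vout[c] += w * cf[oy + kx + c * ncv];
      }
    }
  }
}

// Integrate dp/dt = time_dir * v(p) for unit time with RK4.
// pts are world-mm (axis-aligned frame); origin_mm/spacing_mm describe the
// control grid in the same frame.
// [[Rcpp::export]]
NumericMatrix cpp_flow_points(NumericVector coef, IntegerVector cdim,
                              NumericVector origin_mm, NumericVector spacing_mm,
                              NumericMatrix pts, double time_dir, int nsteps) {
  const int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
  const int n = pts.nrow();
  NumericMatrix out(n, 3);
  const double *cf = coef.begin();
  const double h = time_dir / nsteps;
  for (int i = 0; i < n; ++i) {
    double p[3] = { pts(i, 0), pts(i, 1), pts(i, 2) };
    for (int s = 0; s < nsteps; ++s) {
      double k1[3], k2[3], k3[3], k4[3], q[3];
      auto vel = [&](const double *pp, double *k) {
        spline_at(cf, ncx, ncy, ncz, 3,
                  (pp[0] - origin_mm[0]) / spacing_mm[0],
                  (pp[1] - origin_mm[1]) / spacing_mm[1],
                  (pp[2] - origin_mm[2]) / spacing_mm[2], k);
      };
      vel(p, k1);
      for (int c = 0; c < 3; ++c) q[c] = p[c] + 0.5 * h * k1[c];
      vel(q, k2);
      for (int c = 0; c < 3; ++c) q[c] = p[c] + 0.5 * h * k2[c];
      vel(q, k3);
      for (int c = 0; c < 3; ++c) q[c] = p[c] + h * k3[c];
      vel(q, k4);
      for (int c = 0; c < 3; ++c)
        p[c] += h / 6.0 * (k1[c] + 2.0 * k2[c] + 2.0 * k3[c] + k4[c]);
    }
    for (int c = 0; c < 3; ++c) out(i, c) = p[c];
  }
  return out;
}

// ---------------------------------------------------------------------------
// interpolation / composition / resampling
// ---------------------------------------------------------------------------

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// trilinear sample of component c of a vector field, edge-clamped
static inline double interp_field(const double *f, int nx, int ny, int nz,
                                  size_t nvox, int c,
                                  double x, double y, double z) {
  x = clampd(x, 0.0, nx - 1.0);
  y = clampd(y, 0.0, ny - 1.0);
  z = clampd(z, 0.0, nz - 1.0);
  int x0 = std::min((int)std::floor(x), nx - 2);
  int y0 = std::min((int)std::floor(y), ny - 2);
  int z0 = std::min((int)std::floor(z), nz - 2);
  if (nx == 1) x0 = 0;
  if (ny == 1) y0 = 0;
  if (nz == 1) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const double *fc = f + c * nvox;
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz) {
    double wz = dz ? fz : 1.0 - fz;
    if (nz == 1) { if (dz) continue; wz = 1.0; }
    for (int dy = 0; dy < 2; ++dy) {
      double wy = dy ? fy : 1.0 - fy;
      if (ny == 1) { if (dy) continue; wy = 1.0; }
      for (int dx = 0; dx < 2; ++dx) {
        double wx = dx ? fx : 1.0 - fx;
        if (nx == 1) { if (dx) continue; wx = 1.0; }
        acc += wz * wy * wx *
          fc[((size_t)(z0 + dz) * ny + (y0 + dy)) * nx + (x0 + dx)];
      }
    }
  }
  return acc;
}

// displacement of (f o g): u(p) = u_g(p) + u_f(p + u_g(p))
// fields in mm; spacing converts mm to voxel units for the lookup.
// [[Rcpp::export]]
NumericVector cpp_compose(NumericVector uf, NumericVector ug, IntegerVector dim,
                          NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(3 * nvox);
  const double *pf = uf.begin(), *pg = ug.begin();
  double *o = out.begin();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const size_t i = ((size_t)z * ny + y) * nx + x;
        const double gx = pg[i], gy = pg[i + nvox], gz = pg[i + 2 * nvox];
        const double qx = x + gx / spacing[0];
        const double qy = y + gy / spacing[1];
        const double qz = z + gz / spacing[2];
        o[i]            = gx + interp_field(pf, nx, ny, nz, nvox, 0, qx, qy, qz);
        o[i + nvox]     = gy + interp_field(pf, nx, ny, nz, nvox, 1, qx, qy, qz);
        o[i + 2 * nvox] = gz + interp_field(pf, nx, ny, nz, nvox, 2, qx, qy, qz);
      }
  return out;
}

// scaling-and-squaring exponentiation of +/- v in one call; fields in mm
// [[Rcpp::export]]
List cpp_exp_both(NumericVector vel, IntegerVector dim, NumericVector spacing,
                  int steps) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  const double sc = 1.0 / std::pow(2.0, steps);
  NumericVector fwd(3 * nvox), bwd(3 * nvox);
  std::vector<double> buf(3 * nvox);
  for (size_t i = 0; i < 3 * nvox; ++i) {
    fwd[i] = vel[i] * sc;
    bwd[i] = -fwd[i];
  }
  for (int dirn = 0; dirn < 2; ++dirn) {
    double *u = (dirn == 0) ? fwd.begin() : bwd.begin();
    for (int s = 0; s < steps; ++s) {
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            const size_t i = ((size_t)z * ny + y) * nx + x;
            const double gx = u[i], gy = u[i + nvox], gz = u[i + 2 * nvox];
            const double qx = x + gx / spacing[0];
            const double qy = y + gy / spacing[1];
            const double qz = z + gz / spacing[2];
            buf[i] = gx + interp_field(u, nx, ny, nz, nvox, 0, qx, qy, qz);
            buf[i + nvox] = gy + interp_field(u, nx, ny, nz, nvox, 1, qx, qy, qz);
            buf[i + 2 * nvox] =
              gz + interp_field(u, nx, ny, nz, nvox, 2, qx, qy, qz);
          }
      std::memcpy(u, buf.data(), sizeof(double) * 3 * nvox);
    }
  }
  return List::create(_["forward"] = fwd, _["backward"] = bwd);
}

static inline double keys_w(double t) {
  // Catmull-Rom (Keys a = -0.5) cubic convolution kernel
  t = std::fabs(t);
  if (t < 1.0) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t < 2.0) return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}

// order: 0 nearest, 1 linear, 3 cubic (Catmull-Rom); out-of-volume -> pad
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dim,
                           NumericVector disp, NumericVector spacing,
                           int order, double pad) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(nvox);
  const double *v = vol.begin(), *d = disp.begin();
  double *o = out.begin();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const size_t i = ((size_t)z * ny + y) * nx + x;
        const double qx = x + d[i] / spacing[0];
        const double qy = y + d[i + nvox] / spacing[1];
        const double qz = z + d[i + 2 * nvox] / spacing[2];
        if (qx < 0.0 || qx > nx - 1.0 || qy < 0.0 || qy > ny - 1.0 ||
            qz < 0.0 || qz > nz - 1.0) {
          o[i] = pad;
          continue;
        }
        if (order == 0) {
          int ix = (int)std::lround(qx), iy = (int)std::lround(qy),
              iz = (int)std::lround(qz);
          o[i] = v[((size_t)iz * ny + iy) * nx + ix];
        } else if (order == 1) {
          o[i] = interp_field(v, nx, ny, nz, nvox, 0, qx, qy, qz);
        } else {
          int x0 = (int)std::floor(qx), y0 = (int)std::floor(qy),
              z0 = (int)std::floor(qz);
          double acc = 0.0;
          for (int kz = -1; kz <= 2; ++kz) {
            int iz = std::min(std::max(z0 + kz, 0), nz - 1);
            double wz = keys_w(qz - (z0 + kz));
            if (wz == 0.0) continue;
            for (int ky = -1; ky <= 2; ++ky) {
              int iy = std::min(std::max(y0 + ky, 0), ny - 1);
              double wyz = wz * keys_w(qy - (y0 + ky));
              if (wyz == 0.0) continue;
              for (int kx = -1; kx <= 2; ++kx) {
                int ix = std::min(std::max(x0 + kx, 0), nx - 1);
                double w = wyz * keys_w(qx - (x0 + kx));
                if (w == 0.0) continue;
                acc += w * v[((size_t)iz * ny + iy) * nx + ix];
              }
            }
          }
          o[i] = acc;
        }
      }
  return out;
}

// trilinear field values at continuous voxel coordinates (n x 3), mm output
// [[Rcpp::export]]
NumericMatrix cpp_interp_field_at(NumericVector disp, IntegerVector dim,
                                  NumericMatrix pts_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  const int n = pts_vox.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c)
      out(i, c) = interp_field(disp.begin(), nx, ny, nz, nvox, c,
                               pts_vox(i, 0), pts_vox(i, 1), pts_vox(i, 2));
  return out;
}

// det(I + du/dx) by central differences (one-sided at the border), mm frame
// [[Rcpp::export]]
NumericVector cpp_jacobian_det(NumericVector disp, IntegerVector dim,
                               NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(nvox);
  const double *d = disp.begin();
  double *o = out.begin();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const size_t i = ((size_t)z * ny + y) * nx + x;
        double J[3][3];
        const int xm = std::max(x - 1, 0), xp = std::min(x + 1, nx - 1);
        const int ym = std::max(y - 1, 0), yp = std::min(y + 1, ny - 1);
        const int zm = std::max(z - 1, 0), zp = std::min(z + 1, nz - 1);
        const double hx = (xp - xm) * spacing[0];
        const double hy = (yp - ym) * spacing[1];
        const double hz = (zp - zm) * spacing[2];
        for (int c = 0; c < 3; ++c) {
          const double *dc = d + c * nvox;
          J[c][0] = (dc[((size_t)z * ny + y) * nx + xp] -
                     dc[((size_t)z * ny + y) * nx + xm]) / hx;
          J[c][1] = (dc[((size_t)z * ny + yp) * nx + x] -
                     dc[((size_t)z * ny + ym) * nx + x]) / hy;
          J[c][2] = (dc[((size_t)zp * ny + y) * nx + x] -
                     dc[((size_t)zm * ny + y) * nx + x]) / hz;
        }
        J[0][0] += 1.0; J[1][1] += 1.0; J[2][2] += 1.0;
        o[i] = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
               J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
               J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      }
  return out;
}

// central-difference spatial gradient of a scalar volume (per mm)
// [[Rcpp::export]]
NumericVector cpp_gradient3(NumericVector vol, IntegerVector dim,
                            NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(3 * nvox);
  const double *v = vol.begin();
  double *o = out.begin();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const size_t i = ((size_t)z * ny + y) * nx + x;
        const int xm = std::max(x - 1, 0), xp = std::min(x + 1, nx - 1);
        const int ym = std::max(y - 1, 0), yp = std::min(y + 1, ny - 1);
        const int zm = std::max(z - 1, 0), zp = std::min(z + 1, nz - 1);
        o[i] = (v[((size_t)z * ny + y) * nx + xp] -
                v[((size_t)z * ny + y) * nx + xm]) / ((xp - xm) * spacing[0]);
        o[i + nvox] = (v[((size_t)z * ny + yp) * nx + x] -
                       v[((size_t)z * ny + ym) * nx + x]) / ((yp - ym) * spacing[1]);
        o[i + 2 * nvox] = (v[((size_t)zp * ny + y) * nx + x] -
                           v[((size_t)zm * ny + y) * nx + x]) / ((zp - zm) * spacing[2]);
      }
  return out;
}

// ---------------------------------------------------------------------------
// exact Euclidean distance transform (Felzenszwalb & Huttenlocher), 3D,
// anisotropic spacing.  Returns the distance in mm from every voxel to the
// nearest foreground (mask != 0) voxel centre.
// ---------------------------------------------------------------------------

static const double EDT_FAR = 1e20; // finite sentinel for "no foreground"

static void dt1d(const double *f, double *d, int n, double s) {
  // squared-distance transform of sampled function f with sample spacing s
  std::vector<int> vv(n);
  std::vector<double> zz(n + 1);
  int k = 0;
  vv[0] = 0;
  zz[0] = -std::numeric_limits<double>::infinity();
  zz[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double sq = (double)q * s, sv;
    double fq = f[q];
    double sintersect;
    while (true) {
      sv = (double)vv[k] * s;
      sintersect = ((fq + sq * sq) - (f[vv[k]] + sv * sv)) / (2.0 * sq - 2.0 * sv);
      if (k > 0 && sintersect <= zz[k]) { --k; } else break;
    }
    ++k;
    vv[k] = q;
    zz[k] = sintersect;
    zz[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double sq = (double)q * s;
    while (zz[k + 1] < sq) ++k;
    double sv = (double)vv[k] * s;
    d[q] = (sq - sv) * (sq - sv) + f[vv[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  std::vector<double> d(nvox);
  for (size_t i = 0; i < nvox; ++i) d[i] = mask[i] ? 0.0 : EDT_FAR;
  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> g(f.size());
  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      double *row = &d[((size_t)z * ny + y) * nx];
      dt1d(row, g.data(), nx, spacing[0]);
      std::memcpy(row, g.data(), sizeof(double) * nx);
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = d[((size_t)z * ny + y) * nx + x];
      dt1d(f.data(), g.data(), ny, spacing[1]);
      for (int y = 0; y < ny; ++y) d[((size_t)z * ny + y) * nx + x] = g[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = d[((size_t)z * ny + y) * nx + x];
      dt1d(f.data(), g.data(), nz, spacing[2]);
      for (int z = 0; z < nz; ++z) d[((size_t)z * ny + y) * nx + x] = g[z];
    }
  NumericVector out(nvox);
  for (size_t i = 0; i < nvox; ++i) out[i] = std::sqrt(d[i]);
  return out;
}

// ---------------------------------------------------------------------------
// separable Gaussian smoothing (reflected boundary)
// ---------------------------------------------------------------------------

static void conv1(const std::vector<double> &in, std::vector<double> &out,
                  int n, const std::vector<double> &k) {
  const int r = (int)k.size() / 2;
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = -r; j <= r; ++j) {
      int p = i + j;
      if (p < 0) p = -p - 1;
      if (p >= n) p = 2 * n - p - 1;
      acc += k[j + r] * in[p];
    }
    out[i] = acc;
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian3(NumericVector vol, IntegerVector dim,
                            NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(clone(vol));
  double *v = out.begin();
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma_vox[ax];
    if (s <= 0.0) continue;
    const int r = std::max(1, (int)std::ceil(4.0 * s));
    std::vector<double> k(2 * r + 1);
    double sum = 0.0;
    for (int j = -r; j <= r; ++j) {
      k[j + r] = std::exp(-0.5 * j * j / (s * s));
      sum += k[j + r];
    }
    for (auto &kk : k) kk /= sum;
    const int n = (ax == 0) ? nx : (ax == 1 ? ny : nz);
    std::vector<double> line(n), res(n);
    if (ax == 0) {
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
          double *row = v + ((size_t)z * ny + y) * nx;
          std::copy(row, row + nx, line.begin());
          conv1(line, res, nx, k);
          std::copy(res.begin(), res.end(), row);
        }
    } else if (ax == 1) {
      for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x) {
          for (int y = 0; y < ny; ++y) line[y] = v[((size_t)z * ny + y) * nx + x];
          conv1(line, res, ny, k);
          for (int y = 0; y < ny; ++y) v[((size_t)z * ny + y) * nx + x] = res[y];
        }
    } else {
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          for (int z = 0; z < nz; ++z) line[z] = v[((size_t)z * ny + y) * nx + x];
          conv1(line, res, nz, k);
          for (int z = 0; z < nz; ++z) v[((size_t)z * ny + y) * nx + x] = res[z];
        }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Hessian eigenvalues (for vesselness); central differences, mm frame,
// sorted by increasing |lambda|.
// ---------------------------------------------------------------------------

static void sym3_eigs(double a11, double a22, double a33, double a12,
                      double a13, double a23, double *ev) {
  const double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 == 0.0) {
    ev[0] = a11; ev[1] = a22; ev[2] = a33;
  } else {
    const double q = (a11 + a22 + a33) / 3.0;
    const double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                      (a33 - q) * (a33 - q) + 2.0 * p1;
    const double p = std::sqrt(p2 / 6.0);
    const double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
    const double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
    double detB = b11 * (b22 * b33 - b23 * b23) -
                  b12 * (b12 * b33 - b23 * b13) +
                  b13 * (b12 * b23 - b22 * b13);
    double r = detB / 2.0;
    r = clampd(r, -1.0, 1.0);
    const double phi = std::acos(r) / 3.0;
    const double e1 = q + 2.0 * p * std::cos(phi);
    const double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    const double e2 = 3.0 * q - e1 - e3;
    ev[0] = e1; ev[1] = e2; ev[2] = e3;
  }
  std::sort(ev, ev + 3, [](double a, double b) {
    return std::fabs(a) < std::fabs(b);
  });
}

// [[Rcpp::export]]
List cpp_hessian_eigs(NumericVector vol, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector l1(nvox), l2(nvox), l3(nvox);
  const double *v = vol.begin();
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  auto at = [&](int x, int y, int z) {
    x = std::min(std::max(x, 0), nx - 1);
    y = std::min(std::max(y, 0), ny - 1);
    z = std::min(std::max(z, 0), nz - 1);
    return v[((size_t)z * ny + y) * nx + x];
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const size_t i = ((size_t)z * ny + y) * nx + x;
        const double c = at(x, y, z);
        const double hxx = (at(x + 1, y, z) - 2 * c + at(x - 1, y, z)) / (sx * sx);
        const double hyy = (at(x, y + 1, z) - 2 * c + at(x, y - 1, z)) / (sy * sy);
        const double hzz = (at(x, y, z + 1) - 2 * c + at(x, y, z - 1)) / (sz * sz);
        const double hxy = (at(x + 1, y + 1, z) - at(x + 1, y - 1, z) -
                            at(x - 1, y + 1, z) + at(x - 1, y - 1, z)) /
                           (4.0 * sx * sy);
        const double hxz = (at(x + 1, y, z + 1) - at(x + 1, y, z - 1) -
                            at(x - 1, y, z + 1) + at(x - 1, y, z - 1)) /
                           (4.0 * sx * sz);
        const double hyz = (at(x, y + 1, z + 1) - at(x, y + 1, z - 1) -
                            at(x, y - 1, z + 1) + at(x, y - 1, z - 1)) /
                           (4.0 * sy * sz);
        double ev[3];
        sym3_eigs(hxx, hyy, hzz, hxy, hxz, hyz, ev);
        l1[i] = ev[0]; l2[i] = ev[1]; l3[i] = ev[2];
      }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3);
}

// ---------------------------------------------------------------------------
// NMI with a bin-integrated cubic-spline Parzen window along the warped
// axis.  The per-bin weight is the kernel mass falling inside the bin,
// W_j(wc) = F((b_{j+1}-wc)/h) - F((b_j-wc)/h) with F the cubic B-spline CDF
// and h the bandwidth in bins; with h <= 0.25 an intensity at a bin centre
// contributes to that bin only (hard-binning limit) while the measure stays
// differentiable in the warped intensities.  Reference intensities are
// hard-binned; entropies use natural logs.
// ---------------------------------------------------------------------------

// CDF of the cubic B-spline kernel (support [-2, 2])
static inline double bspline_cdf(double t) {
  if (t <= -2.0) return 0.0;
  if (t >= 2.0) return 1.0;
  if (t <= -1.0) { double u = 2.0 + t; return u * u * u * u / 24.0; }
  if (t <= 0.0)
    return 0.5 + (4.0 * t - 2.0 * t * t * t - 0.75 * t * t * t * t) / 6.0;
  if (t <= 1.0)
    return 0.5 + (4.0 * t - 2.0 * t * t * t + 0.75 * t * t * t * t) / 6.0;
  double u = 2.0 - t;
  return 1.0 - u * u * u * u / 24.0;
}

static inline double bspline_pdf(double t) {
  double a = std::fabs(t);
  if (a >= 2.0) return 0.0;
  if (a <= 1.0) return (4.0 - 6.0 * a * a + 3.0 * a * a * a) / 6.0;
  double u = 2.0 - a;
  return u * u * u / 6.0;
}

// [[Rcpp::export]]
List cpp_nmi(NumericVector ref, NumericVector wrp, IntegerVector mask,
             int bins, double rmin, double rmax, double wmin, double wmax,
             double bandwidth, bool want_grad) {
  const size_t n = ref.size();
  const double rs = (bins - 1e-9) / std::max(rmax - rmin, 1e-12);
  const double ws = (double)bins / std::max(wmax - wmin, 1e-12);
  const double h = std::max(bandwidth, 1e-3);
  std::vector<double> H((size_t)bins * bins, 0.0);
  std::vector<int> rb(n, -1);
  std::vector<double> wc(n, 0.0);
  double N = 0.0;
  const int halfspan = (int)std::ceil(2.0 * h) + 1;
  for (size_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int ri = (int)std::floor((ref[i] - rmin) * rs);
    ri = std::min(std::max(ri, 0), bins - 1);
    // continuous bin coordinate of the warped intensity (bin j covers
    // [j, j+1); a value at a bin centre has wc = j + 0.5)
    double wci = (wrp[i] - wmin) * ws;
    rb[i] = ri;
    wc[i] = wci;
    int jc = std::min(std::max((int)std::floor(wci), 0), bins - 1);
    for (int j = std::max(jc - halfspan, 0);
         j <= std::min(jc + halfspan, bins - 1); ++j) {
      // only the outermost real bins are open-ended (they absorb the tails)
      double lo = (j == 0) ? -1e30 : ((double)j - wci) / h;
      double hi = (j == bins - 1) ? 1e30 : ((double)j + 1.0 - wci) / h;
      double w = bspline_cdf(hi) - bspline_cdf(lo);
      if (w <= 0.0) continue;
      H[(size_t)ri * bins + j] += w;
    }
    N += 1.0;
  }
  if (N < 1.0) stop("empty evaluation mask");
  std::vector<double> pR(bins, 0.0), pW(bins, 0.0);
  double HR = 0.0, HW = 0.0, HRW = 0.0;
  for (int i = 0; i < bins; ++i)
    for (int j = 0; j < bins; ++j) {
      double p = H[(size_t)i * bins + j] / N;
      pR[i] += p;
      pW[j] += p;
      if (p > 0.0) HRW -= p * std::log(p);
    }
  for (int i = 0; i < bins; ++i) {
    if (pR[i] > 0.0) HR -= pR[i] * std::log(pR[i]);
    if (pW[i] > 0.0) HW -= pW[i] * std::log(pW[i]);
  }
  const double nmi = (HRW > 1e-12) ? (HR + HW) / HRW : 2.0;
  NumericVector grad;
  if (want_grad) {
    grad = NumericVector(n);
    std::vector<double> logW(bins, 0.0), logJ((size_t)bins * bins, 0.0);
    for (int j = 0; j < bins; ++j)
      logW[j] = (pW[j] > 0.0) ? std::log(pW[j]) : 0.0;
    for (size_t ij = 0; ij < (size_t)bins * bins; ++ij)
      logJ[ij] = (H[ij] > 0.0) ? std::log(H[ij] / N) : 0.0;
    for (size_t i = 0; i < n; ++i) {
      if (rb[i] < 0) { grad[i] = 0.0; continue; }
      const double wci = wc[i];
      int jc = std::min(std::max((int)std::floor(wci), 0), bins - 1);
      double dHW = 0.0, dHRW = 0.0;
      for (int j = std::max(jc - halfspan, 0);
           j <= std::min(jc + halfspan, bins - 1); ++j) {
        // dW_j/dw = -(k(hi) - k(lo)) / h * ws, outer bins open-ended
        double klo = (j == 0) ? 0.0 : bspline_pdf(((double)j - wci) / h);
        double khi = (j == bins - 1) ? 0.0
                     : bspline_pdf(((double)j + 1.0 - wci) / h);
        double dw = -(khi - klo) / h * ws;
        if (dw == 0.0) continue;
        const double dp = dw / N;
        dHW -= dp * (1.0 + logW[j]);
        dHRW -= dp * (1.0 + logJ[(size_t)rb[i] * bins + j]);
      }
      grad[i] = (dHW - nmi * dHRW) / std::max(HRW, 1e-12);
    }
  }
  return List::create(_["value"] = nmi, _["grad"] = grad, _["n"] = N,
                      _["HR"] = HR, _["HW"] = HW, _["HRW"] = HRW);
}

// ---------------------------------------------------------------------------
// block matching (rigid initialisation): exhaustive integer NCC search
// ---------------------------------------------------------------------------

// corners: m x 3 zero-based block corner indices in the reference image.
// Returns per-block best displacement (voxels) and NCC.
// [[Rcpp::export]]
List cpp_block_match(NumericVector ref, NumericVector flt, IntegerVector dim,
                     IntegerMatrix corners, int block, int search) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int m = corners.nrow();
  NumericMatrix disp(m, 3);
  NumericVector score(m);
  const double *R = ref.begin(), *F = flt.begin();
  const int nb = block * block * block;
  std::vector<double> rblk(nb), fblk(nb);
  for (int b = 0; b < m; ++b) {
    const int cx = corners(b, 0), cy = corners(b, 1), cz = corners(b, 2);
    double rmean = 0.0;
    for (int z = 0; z < block; ++z)
      for (int y = 0; y < block; ++y)
        for (int x = 0; x < block; ++x) {
          double v = R[((size_t)(cz + z) * ny + (cy + y)) * nx + (cx + x)];
          rblk[(z * block + y) * block + x] = v;
          rmean += v;
        }
    rmean /= nb;
    double rvar = 0.0;
    for (int i = 0; i < nb; ++i) {
      rblk[i] -= rmean;
      rvar += rblk[i] * rblk[i];
    }
    double best = -2.0;
    int bdx = 0, bdy = 0, bdz = 0;
    for (int dz = -search; dz <= search; ++dz)
      for (int dy = -search; dy <= search; ++dy)
        for (int dx = -search; dx <= search; ++dx) {
          const int ox = cx + dx, oy = cy + dy, oz = cz + dz;
          if (ox < 0 || oy < 0 || oz < 0 || ox + block > nx ||
              oy + block > ny || oz + block > nz)
            continue;
          double fmean = 0.0;
          for (int z = 0; z < block; ++z)
            for (int y = 0; y < block; ++y)
              for (int x = 0; x < block; ++x) {
                double v = F[((size_t)(oz + z) * ny + (oy + y)) * nx + (ox + x)];
                fblk[(z * block + y) * block + x] = v;
                fmean += v;
              }
          fmean /= nb;
          double fvar = 0.0, cov = 0.0;
          for (int i = 0; i < nb; ++i) {
            const double fv = fblk[i] - fmean;
            fvar += fv * fv;
            cov += fv * rblk[i];
          }
          if (rvar <= 1e-12 || fvar <= 1e-12) continue;
          const double ncc = cov / std::sqrt(rvar * fvar);
          if (ncc > best) {
            best = ncc;
            bdx = dx; bdy = dy; bdz = dz;
          }
        }
    disp(b, 0) = bdx; disp(b, 1) = bdy; disp(b, 2) = bdz;
    score[b] = best;
  }
  return List::create(_["disp"] = disp, _["score"] = score);
}
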