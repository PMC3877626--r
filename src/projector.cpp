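#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parallel-beam ray marching with bilinear sampling (Joseph-style), plus its
// exact transpose, and separable 1D convolutions used for Gaussian/box
// filtering of volumes.  All loops are transaxial-slice-parallel: slice k of
// the volume maps to slice k of the sinogram stack.
//
// Conventions
//   - volume dims (nx, ny, nz), column-major as in R
//   - pixel (i, j) center at ((i + 0.5 - nx/2) * dx, (j + 0.5 - ny/2) * dy)
//     relative to the rotation center (image center)
//   - sinogram dims (n_angles, n_radial, nz); radial bin r has signed offset
//     s_r = (r - (n_radial - 1) / 2) * ds
//   - ray for (angle th, offset s): p(t) = s * (cos th, sin th)
//                                        + t * (-sin th, cos th)
//   - forward integrates image values along t with step dt (mm), weight dt

static inline void clip_ray(double s, double co, double si,
                            double hx, double hy,
                            double &tmin, double &tmax) {
  // intersect p(t) with the slab |x| <= hx, |y| <= hy
  tmin = -1e30; tmax = 1e30;
  // x(t) = s*co - t*si
  if (std::fabs(si) > 1e-12) {
    double t1 = (s * co - hx) / si, t2 = (s * co + hx) / si;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1); tmax = std::min(tmax, t2);
  } else if (std::fabs(s * co) > hx) { tmax = tmin - 1.0; return; }
  // y(t) = s*si + t*co
  if (std::fabs(co) > 1e-12) {
    double t1 = (-hy - s * si) / co, t2 = (hy - s * si) / co;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1); tmax = std::min(tmax, t2);
  } else if (std::fabs(s * si) > hy) { tmax = tmin - 1.0; return; }
}

// [[Rcpp::export(name = ".forward_project_cpp")]]
NumericVector forward_project_cpp(NumericVector vol, IntegerVector dims,
                                  double dx, double dy,
                                  NumericVector angles, int n_radial,
                                  double ds, double step) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = angles.size();
  const double hx = nx * dx / 2.0, hy = ny * dy / 2.0;
  const double s0 = (n_radial - 1) / 2.0;
  NumericVector sino(static_cast<R_xlen_t>(na) * n_radial * nz);
  const double *v = vol.begin();
  double *out = sino.begin();

  for (int a = 0; a < na; ++a) {
    const double co = std::cos(angles[a]), si = std::sin(angles[a]);
    for (int r = 0; r < n_radial; ++r) {
      const double s = (r - s0) * ds;
      double tmin, tmax;
      clip_ray(s, co, si, hx + dx, hy + dy, tmin, tmax);
      if (tmax <= tmin) continue;
      const int nstep = (int)std::ceil((tmax - tmin) / step);
      const double dt = (tmax - tmin) / nstep;
      for (int k = 0; k < nz; ++k) {
        const double *slice = v + static_cast<R_xlen_t>(k) * nx * ny;
        double acc = 0.0;
        for (int m = 0; m < nstep; ++m) {
          const double t = tmin + (m + 0.5) * dt;
          const double x = s * co - t * si, y = s * si + t * co;
          // fractional pixel index
          const double fx = x / dx + nx / 2.0 - 0.5;
          const double fy = y / dy + ny / 2.0 - 0.5;
          const int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy);
          if (i0 < -1 || i0 > nx - 1 || j0 < -1 || j0 > ny - 1) continue;
          const double wx = fx - i0, wy = fy - j0;
          double val = 0.0;
          if (i0 >= 0 && j0 >= 0)           val += (1 - wx) * (1 - wy) * slice[i0 + j0 * nx];
          if (i0 + 1 < nx && j0 >= 0)       val += wx * (1 - wy) * slice[i0 + 1 + j0 * nx];
          if (i0 >= 0 && j0 + 1 < ny)       val += (1 - wx) * wy * slice[i0 + (j0 + 1) * nx];
          if (i0 + 1 < nx && j0 + 1 < ny)   val += wx * wy * slice[i0 + 1 + (j0 + 1) * nx];
          acc += val;
        }
        out[a + static_cast<R_xlen_t>(r) * na +
            static_cast<R_xlen_t>(k) * na * n_radial] += acc * dt;
      }
    }
  }
  sino.attr("dim") = IntegerVector::create(na, n_radial, nz);
  return sino;
}

// Exact transpose of forward_project_cpp: scatters sino[a, r, k] * dt with the
// same bilinear weights along the same sample points.
// [[Rcpp::export(name = ".backproject_cpp")]]
NumericVector backproject_cpp(NumericVector sino, IntegerVector sdims,
                              int nx, int ny,
                              double dx, double dy,
                              NumericVector angles, double ds, double step) {
  const int na = sdims[0], n_radial = sdims[1], nz = sdims[2];
  const double hx = nx * dx / 2.0, hy = ny * dy / 2.0;
  const double s0 = (n_radial - 1) / 2.0;
  NumericVector vol(static_cast<R_xlen_t>(nx) * ny * nz);
  const double *q = sino.begin();
  double *v = vol.begin();

  for (int a = 0; a < na; ++a) {
    const double co = std::cos(angles[a]), si = std::sin(angles[a]);
    for (int r = 0; r < n_radial; ++r) {
      const double s = (r - s0) * ds;
      double tmin, tmax;
      clip_ray(s, co, si, hx + dx, hy + dy, tmin, tmax);
      if (tmax <= tmin) continue;
      const int nstep = (int)std::ceil((tmax - tmin) / step);
      const double dt = (tmax - tmin) / nstep;
      for (int k = 0; k < nz; ++k) {
        double *slice = v + static_cast<R_xlen_t>(k) * nx * ny;
        const double qv = q[a + static_cast<R_xlen_t>(r) * na +
                            static_cast<R_xlen_t>(k) * na * n_radial] * dt;
        if (qv == 0.0) continue;
        for (int m = 0; m < nstep; ++m) {
          const double t = tmin + (m + 0.5) * dt;
          const double x = s * co - t * si, y = s * si + t * co;
          const double fx = x / dx + nx / 2.0 - 0.5;
          const double fy = y / dy + ny / 2.0 - 0.5;
          const int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy);
          if (i0 < -1 || i0 > nx - 1 || j0 < -1 || j0 > ny - 1) continue;
          const double wx = fx - i0, wy = fy - j0;
          if (i0 >= 0 && j0 >= 0)           slice[i0 + j0 * nx] += (1 - wx) * (1 - wy) * qv;
          if (i0 + 1 < nx && j0 >= 0)       slice[i0 + 1 + j0 * nx] += wx * (1 - wy) * qv;
          if (i0 >= 0 && j0 + 1 < ny)       slice[i0 + (j0 + 1) * nx] += (1 - wx) * wy * qv;
          if (i0 + 1 < nx && j0 + 1 < ny)   slice[i0 + 1 + (j0 + 1) * nx] += wx * wy * qv;
        }
      }
    }
  }
  vol.attr("dim") = IntegerVector::create(nx, ny, nz);
  return vol;
}

// Separable 1D convolution of a 3D array along one axis with a given kernel.
// Edge handling: replicate (clamp) or zero.
// [[Rcpp::export(name = ".conv_axis_cpp")]]
NumericVector conv_axis_cpp(NumericVector vol, IntegerVector dims,
                            NumericVector kernel, int axis, bool replicate) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int kl = kernel.size(), kh = (kl - 1) / 2;
  NumericVector out(vol.size());
  out.attr("dim") = dims;
  const double *v = vol.begin();
  double *o = out.begin();
  const int n[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int nax = n[axis];
  const R_xlen_t sax = strides[axis];
  // iterate over all lines along `axis`
  const int nb = (axis == 0) ? ny : nx;
  const int nc = (axis == 2) ? ny : nz;
  const R_xlen_t sb = (axis == 0) ? strides[1] : strides[0];
  const R_xlen_t sc = (axis == 2) ? strides[1] : strides[2];
  for (int c = 0; c < nc; ++c) {
    for (int b = 0; b < nb; ++b) {
      const R_xlen_t base = b * sb + c * sc;
      for (int i = 0; i < nax; ++i) {
        double acc = 0.0;
        for (int m = 0; m < kl; ++m) {
          int idx = i + m - kh;
          if (replicate) idx = std::min(std::max(idx, 0), nax - 1);
          else if (idx < 0 || idx >= nax) continue;
          acc += kernel[m] * v[base + idx * sax];
        }
        o[base + i * sax] = acc;
      }
    }
  }
  return out;
}

// Trilinear sampling of a 3D array at fractional (1-based) voxel indices,
// clamped to the grid (replicate edges).
// [[Rcpp::export(name = ".trilinear_cpp")]]
NumericVector trilinear_cpp(NumericVector vol, IntegerVector dims,
                            NumericVector xi, NumericVector yi, NumericVector zi) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t np = xi.size();
  NumericVector out(np);
  const double *v = vol.begin();
  for (R_xlen_t p = 0; p < np; ++p) {
    double fx = xi[p] - 1.0, fy = yi[p] - 1.0, fz = zi[p] - 1.0;
    fx = std::min(std::max(fx, 0.0), (double)(nx - 1));
    fy = std::min(std::max(fy, 0.0), (double)(ny - 1));
    fz = std::min(std::max(fz, 0.0), (double)(nz - 1));
    int i0 = std::min((int)std::floor(fx), nx - 2); if (nx == 1) i0 = 0;
    int j0 = std::min((int)std::floor(fy), ny - 2); if (ny == 1) j0 = 0;
    int k0 = std::min((int)std::floor(fz), nz - 2); if (nz == 1) k0 = 0;
    const double wx = fx - i0, wy = fy - j0, wz = fz - k0;
    const int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
              k1 = std::min(k0 + 1, nz - 1);
    auto at = [&](int i, int j, int k) {
      return v[i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny];
    };
    out[p] =
      (1 - wz) * ((1 - wy) * ((1 - wx) * at(i0, j0, k0) + wx * at(i1, j0, k0)) +
                  wy * ((1 - wx) * at(i0, j1, k0) + wx * at(i1, j1, k0))) +
      wz * ((1 - wy) * ((1 - wx) * at(i0, j0, k1) + wx * at(i1, j0, k1)) +
            wy * ((1 - wx) * at(i0, j1, k1) + wx * at(i1, j1, k1)));
  }
  return out;
}
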