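#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>
using namespace Rcpp;

// Voxel layout: R arrays with dim = (nx, ny, nz), x fastest (column-major).
// Linear index l = i + nx*(j + ny*k), all 0-based here, 1-based on the R side.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher 2012),
// separable lower-envelope scan per axis with anisotropic voxel spacing.
// Input: logical mask; output: squared distance (mm^2) from every voxel to
// the nearest TRUE voxel. All-false mask -> +Inf everywhere.
// ---------------------------------------------------------------------------
static void edt1d(std::vector<double> &f, std::vector<double> &d,
                  std::vector<int> &v, std::vector<double> &z,
                  int n, double w2) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)(q - v[k]);
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d_sq(LogicalVector mask, IntegerVector dim,
                           NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  // large finite sentinel: infinities break the parabola intersections
  const double INF = 1e12;
  NumericVector out((R_xlen_t)nx * ny * nz);
  // init: 0 on mask, Inf off mask
  for (R_xlen_t l = 0; l < out.size(); l++)
    out[l] = mask[l] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  double w2 = spacing[0] * spacing[0];
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      bool any_finite = false;
      for (int i = 0; i < nx; i++) { f[i] = out[base + i]; if (f[i] < INF) any_finite = true; }
      if (!any_finite) continue;
      edt1d(f, d, v, z, nx, w2);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }
  // pass along y
  w2 = spacing[1] * spacing[1];
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      bool any_finite = false;
      for (int j = 0; j < ny; j++) { f[j] = out[base + (R_xlen_t)nx * j]; if (f[j] < INF) any_finite = true; }
      if (!any_finite) continue;
      edt1d(f, d, v, z, ny, w2);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // pass along z
  w2 = spacing[2] * spacing[2];
  const R_xlen_t stepz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      bool any_finite = false;
      for (int k = 0; k < nz; k++) { f[k] = out[base + stepz * k]; if (f[k] < INF) any_finite = true; }
      if (!any_finite) continue;
      edt1d(f, d, v, z, nz, w2);
      for (int k = 0; k < nz; k++) out[base + stepz * k] = d[k];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear interpolation of a scalar volume at continuous 0-based index
// coordinates; out-of-grid points are clamped to the boundary (nearest edge
// value), matching the boundary policy documented for dose/field sampling.
// pts: n x 3 matrix of 0-based (ix, iy, iz).
// ---------------------------------------------------------------------------
static inline double trilinear_one(const double *vol, int nx, int ny, int nz,
                                   double x, double y, double z) {
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  i0 = clampi(i0, 0, nx - 1); j0 = clampi(j0, 0, ny - 1); k0 = clampi(k0, 0, nz - 1);
  int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
      k1 = std::min(k0 + 1, nz - 1);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
#define V(I, J, K) vol[(I) + (R_xlen_t)nx * (J) + sxy * (K)]
  double c00 = V(i0, j0, k0) * (1 - fx) + V(i1, j0, k0) * fx;
  double c10 = V(i0, j1, k0) * (1 - fx) + V(i1, j1, k0) * fx;
  double c01 = V(i0, j0, k1) * (1 - fx) + V(i1, j0, k1) * fx;
  double c11 = V(i0, j1, k1) * (1 - fx) + V(i1, j1, k1) * fx;
#undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (int p = 0; p < n; p++)
    out[p] = trilinear_one(v, nx, ny, nz, pts(p, 0), pts(p, 1), pts(p, 2));
  return out;
}

// Sample a 3-component displacement field (dim nx*ny*nz*3) at continuous
// 0-based index coordinates. Returns n x 3 matrix (same units as field).
// [[Rcpp::export]]
NumericMatrix cpp_sample_field(NumericVector field, IntegerVector dim,
                               NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t ncomp = (R_xlen_t)nx * ny * nz;
  const int n = pts.nrow();
  NumericMatrix out(n, 3);
  const double *f = REAL(field);
  for (int c = 0; c < 3; c++) {
    const double *vc = f + ncomp * c;
    for (int p = 0; p < n; p++)
      out(p, c) = trilinear_one(vc, nx, ny, nz, pts(p, 0), pts(p, 1), pts(p, 2));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fixed-point inversion of a displacement field u (mm, planning -> fraction):
// find v with v(q) = -u(q + v(q)) for every voxel center q, i.e.
// (id + u) o (id + v) ~= id. Iterates v <- -u(q + v) with trilinear sampling
// of u; returns field of same shape. spacing/origin give the world frame.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_invert_field(NumericVector field, IntegerVector dim,
                      NumericVector spacing, int maxit, double tol_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector inv((R_xlen_t)nvox * 3);
  const double *u = REAL(field);
  const double *ux = u, *uy = u + nvox, *uz = u + 2 * nvox;
  double *vx = REAL(inv), *vy = REAL(inv) + nvox, *vz = REAL(inv) + 2 * nvox;
  // start at v = -u(q)
  for (R_xlen_t l = 0; l < nvox; l++) {
    vx[l] = -ux[l]; vy[l] = -uy[l]; vz[l] = -uz[l];
  }
  double maxchg = 0.0;
  int it = 0;
  for (it = 0; it < maxit; it++) {
    maxchg = 0.0;
    R_xlen_t l = 0;
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++, l++) {
          double px = i + vx[l] / spacing[0];
          double py = j + vy[l] / spacing[1];
          double pz = k + vz[l] / spacing[2];
          double nxv = -trilinear_one(ux, nx, ny, nz, px, py, pz);
          double nyv = -trilinear_one(uy, nx, ny, nz, px, py, pz);
          double nzv = -trilinear_one(uz, nx, ny, nz, px, py, pz);
          double chg = std::abs(nxv - vx[l]) + std::abs(nyv - vy[l]) +
                       std::abs(nzv - vz[l]);
          if (chg > maxchg) maxchg = chg;
          vx[l] = nxv; vy[l] = nyv; vz[l] = nzv;
        }
    if (maxchg < tol_mm) { it++; break; }
  }
  // residual of composition: r(q) = v(q) + u(q + v(q)), RMS over voxels
  double ss = 0.0;
  double worst = 0.0;
  R_xlen_t l = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, l++) {
        double px = i + vx[l] / spacing[0];
        double py = j + vy[l] / spacing[1];
        double pz = k + vz[l] / spacing[2];
        double rx = vx[l] + trilinear_one(ux, nx, ny, nz, px, py, pz);
        double ry = vy[l] + trilinear_one(uy, nx, ny, nz, px, py, pz);
        double rz = vz[l] + trilinear_one(uz, nx, ny, nz, px, py, pz);
        double r2 = rx * rx + ry * ry + rz * rz;
        ss += r2;
        if (r2 > worst) worst = r2;
      }
  double rms = std::sqrt(ss / (double)nvox);
  return List::create(_["field"] = inv, _["rms_mm"] = rms,
                      _["worst_mm"] = std::sqrt(worst),
                      _["iterations"] = it, _["last_change_mm"] = maxchg);
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing, sigma given in voxels per axis, kernel
// truncated at 3 sigma, renormalized at the borders (no implicit zero pad).
// ---------------------------------------------------------------------------
static void smooth_axis(std::vector<double> &buf, std::vector<double> &tmp,
                        const std::vector<double> &kern, int n, int radius) {
  for (int q = 0; q < n; q++) {
    double s = 0.0, wsum = 0.0;
    int lo = std::max(0, q - radius), hi = std::min(n - 1, q + radius);
    for (int t = lo; t <= hi; t++) {
      double w = kern[t - q + radius];
      s += w * buf[t];
      wsum += w;
    }
    tmp[q] = s / wsum;
  }
  for (int q = 0; q < n; q++) buf[q] = tmp[q];
}

// [[Rcpp::export]]
NumericVector cpp_smooth3d(NumericVector vol, IntegerVector dim,
                           NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(vol);
  double *o = REAL(out);
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> buf(nmax), tmp(nmax);
  const R_xlen_t stepz = (R_xlen_t)nx * ny;

  for (int ax = 0; ax < 3; ax++) {
    double sg = sigma_vox[ax];
    if (sg <= 0) continue;
    int radius = std::max(1, (int)std::ceil(3.0 * sg));
    std::vector<double> kern(2 * radius + 1);
    for (int t = -radius; t <= radius; t++)
      kern[t + radius] = std::exp(-0.5 * (t / sg) * (t / sg));
    if (ax == 0) {
      for (int k = 0; k < nz; k++)
        for (int j = 0; j < ny; j++) {
          R_xlen_t base = (R_xlen_t)nx * j + stepz * k;
          for (int i = 0; i < nx; i++) buf[i] = o[base + i];
          smooth_axis(buf, tmp, kern, nx, radius);
          for (int i = 0; i < nx; i++) o[base + i] = buf[i];
        }
    } else if (ax == 1) {
      for (int k = 0; k < nz; k++)
        for (int i = 0; i < nx; i++) {
          R_xlen_t base = i + stepz * k;
          for (int j = 0; j < ny; j++) buf[j] = o[base + (R_xlen_t)nx * j];
          smooth_axis(buf, tmp, kern, ny, radius);
          for (int j = 0; j < ny; j++) o[base + (R_xlen_t)nx * j] = buf[j];
        }
    } else {
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          R_xlen_t base = i + (R_xlen_t)nx * j;
          for (int k = 0; k < nz; k++) buf[k] = o[base + stepz * k];
          smooth_axis(buf, tmp, kern, nz, radius);
          for (int k = 0; k < nz; k++) o[base + stepz * k] = buf[k];
        }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Warp a binary mask through a displacement field by nearest-neighbour
// resampling: out(q) = mask(round(q + v(q))), v in mm, the field passed here
// being the inverse (fraction -> planning) displacement. Out-of-grid -> FALSE.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_warp_mask_nn(LogicalVector mask, NumericVector field,
                               IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  LogicalVector out(nvox);
  const double *vx = REAL(field), *vy = REAL(field) + nvox,
               *vz = REAL(field) + 2 * nvox;
  R_xlen_t l = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, l++) {
        int si = (int)std::lround(i + vx[l] / spacing[0]);
        int sj = (int)std::lround(j + vy[l] / spacing[1]);
        int sk = (int)std::lround(k + vz[l] / spacing[2]);
        if (si < 0 || si >= nx || sj < 0 || sj >= ny || sk < 0 || sk >= nz)
          out[l] = FALSE;
        else
          out[l] = mask[si + (R_xlen_t)nx * sj + (R_xlen_t)nx * ny * sk];
      }
  return out;
}

// ---------------------------------------------------------------------------
// Pull a dose grid through a displacement field: out(q) = dose(q + u(q)),
// trilinear, boundary-clamped. Also reports how many sample points left the
// grid (were clamped).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_pull_dose(NumericVector dose, NumericVector field, IntegerVector dim,
                   NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox);
  const double *d = REAL(dose);
  const double *vx = REAL(field), *vy = REAL(field) + nvox,
               *vz = REAL(field) + 2 * nvox;
  int n_clamped = 0;
  R_xlen_t l = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, l++) {
        double px = i + vx[l] / spacing[0];
        double py = j + vy[l] / spacing[1];
        double pz = k + vz[l] / spacing[2];
        if (px < 0 || px > nx - 1 || py < 0 || py > ny - 1 || pz < 0 ||
            pz > nz - 1)
          n_clamped++;
        out[l] = trilinear_one(d, nx, ny, nz, px, py, pz);
      }
  return List::create(_["dose"] = out, _["n_clamped"] = n_clamped);
}

// ---------------------------------------------------------------------------
// Gamma index (global normalization), exhaustive search on the voxel lattice
// within a world-space radius. For each ROI voxel p of the reference with
// ref(p) >= threshold:
//   gamma(p) = min over lattice offsets r, |r| <= search_mm, of
//              sqrt( (eval(p+r) - ref(p))^2 / dd^2 + |r|^2 / dta^2 )
// dd and threshold are absolute doses (Gy). Returns gamma per voxel, NA
// outside the evaluated set. Offsets are scanned in order of increasing
// distance with early termination once the distance term alone exceeds the
// running minimum.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_gamma(NumericVector ref, NumericVector eval,
                        IntegerVector dim, NumericVector spacing,
                        LogicalVector roi, double dta_mm, double dd_abs,
                        double threshold_abs, double search_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double *rf = REAL(ref), *ev = REAL(eval);
  NumericVector out(nvox, NA_REAL);

  // precompute lattice offsets within search radius, sorted by distance
  int rx = (int)std::floor(search_mm / spacing[0]);
  int ry = (int)std::floor(search_mm / spacing[1]);
  int rz = (int)std::floor(search_mm / spacing[2]);
  struct Off { int di, dj, dk; double d2; };
  std::vector<Off> offs;
  for (int dk = -rz; dk <= rz; dk++)
    for (int dj = -ry; dj <= ry; dj++)
      for (int di = -rx; di <= rx; di++) {
        double d2 = di * spacing[0] * di * spacing[0] +
                    dj * spacing[1] * dj * spacing[1] +
                    dk * spacing[2] * dk * spacing[2];
        if (d2 <= search_mm * search_mm) offs.push_back({di, dj, dk, d2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Off &a, const Off &b) { return a.d2 < b.d2; });

  const double dta2 = dta_mm * dta_mm, dd2 = dd_abs * dd_abs;
  R_xlen_t l = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, l++) {
        if (!roi[l] || rf[l] < threshold_abs) continue;
        double best = std::numeric_limits<double>::infinity();
        for (const Off &o : offs) {
          double dist_term = o.d2 / dta2;
          if (dist_term >= best) break;  // sorted: no better offset follows
          int si = i + o.di, sj = j + o.dj, sk = k + o.dk;
          if (si < 0 || si >= nx || sj < 0 || sj >= ny || sk < 0 || sk >= nz)
            continue;
          double dd = ev[si + (R_xlen_t)nx * sj + (R_xlen_t)nx * ny * sk] - rf[l];
          double g2 = dd * dd / dd2 + dist_term;
          if (g2 < best) best = g2;
        }
        out[l] = std::sqrt(best);
      }
  return out;
}
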