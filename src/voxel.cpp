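// Voxel-grid kernels: exact Euclidean distance transform and spatially
// varying (ellipsoidal) dilation for local margin fields.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Felzenszwalb & Huttenlocher 1-D squared distance transform
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n,
                 double step2) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + step2 * q * q) - (f[v[k]] + step2 * v[k] * v[k])) /
          (2.0 * step2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = step2 * dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (mm^2) to the foreground of a binary
// volume, per voxel center, under anisotropic spacing.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dims,
                     NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  // large finite sentinel keeps the parabola intersections well-defined
  const double INF = 1e30;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  double sx2 = spacing[0] * spacing[0];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)k * nx * ny + (size_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, v, z, nx, sx2);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // pass along y
  double sy2 = spacing[1] * spacing[1];
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (size_t)j * nx];
      dt1d(f, d, v, z, ny, sy2);
      for (int j = 0; j < ny; ++j) g[base + (size_t)j * nx] = d[j];
    }
  // pass along z
  double sz2 = spacing[2] * spacing[2];
  size_t slab = (size_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = g[base + (size_t)k * slab];
      dt1d(f, d, v, z, nz, sz2);
      for (int k = 0; k < nz; ++k) g[base + (size_t)k * slab] = d[k];
    }
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = g[i];
  return out;
}

// Spatially varying ellipsoidal dilation: every surface point x (0-based
// voxel indices) stamps the axis-aligned ellipsoid with per-axis radii
// r(x) (mm); a voxel joins the output when || (v - x) * spacing / r || <= 1.
// Zero radii collapse the ellipsoid to the point along that axis.
// [[Rcpp::export(name = ".stamp_ellipsoids")]]
LogicalVector stamp_ellipsoids(IntegerVector dims, NumericVector spacing,
                               IntegerMatrix pts, NumericMatrix radii) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  LogicalVector out(n);
  int np = pts.nrow();
  for (int p = 0; p < np; ++p) {
    double rx = radii(p, 0), ry = radii(p, 1), rz = radii(p, 2);
    int wx = (int)std::floor(rx / spacing[0] + 1e-9);
    int wy = (int)std::floor(ry / spacing[1] + 1e-9);
    int wz = (int)std::floor(rz / spacing[2] + 1e-9);
    int cx = pts(p, 0), cy = pts(p, 1), cz = pts(p, 2);
    for (int dz = -wz; dz <= wz; ++dz) {
      int z = cz + dz;
      if (z < 0 || z >= nz) continue;
      double tz = rz > 0 ? dz * spacing[2] / rz : 0.0;
      for (int dy = -wy; dy <= wy; ++dy) {
        int y = cy + dy;
        if (y < 0 || y >= ny) continue;
        double ty = ry > 0 ? dy * spacing[1] / ry : 0.0;
        for (int dx = -wx; dx <= wx; ++dx) {
          int x = cx + dx;
          if (x < 0 || x >= nx) continue;
          double tx = rx > 0 ? dx * spacing[0] / rx : 0.0;
          if (tx * tx + ty * ty + tz * tz <= 1.0 + 1e-12)
            out[(size_t)z * nx * ny + (size_t)y * nx + x] = true;
        }
      }
    }
  }
  return out;
}
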