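#include <Rcpp.h>
#include <vector>
#include <limits>

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable: one pass of the 1-D lower-envelope-of-parabolas transform per
// axis, with per-axis sample spacing so anisotropic voxels are respected.
// Distances are voxel-center to voxel-center, in physical units (mm).

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform of sampled function f at abscissae i*w.
// Parabolas with f == INF (no source anywhere on the line yet) are skipped.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  std::vector<int> v(n);       // envelope parabola indices
  std::vector<double> z(n + 1); // envelope breakpoints
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    const double xq = q * w;
    double s = -INF;
    while (k >= 0) {
      const double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    const double x = q * w;
    while (z[j + 1] < x) ++j;
    const double dx = x - v[j] * w;
    d[q] = dx * dx + f[v[j]];
  }
}

// [[Rcpp::export(name = ".edt_squared")]]
Rcpp::NumericVector edt_squared(Rcpp::LogicalVector mask,
                                Rcpp::IntegerVector dim,
                                Rcpp::NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (mask[i] == TRUE) ? 0.0 : INF;

  std::vector<double> f, d;

  // pass along x (fastest-varying index)
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }

  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }

  // pass along z
  f.resize(nz); d.resize(nz);
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = out[base + (R_xlen_t)z * nxy];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nxy] = d[z];
    }

  out.attr("dim") = dim;
  return out;
}
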