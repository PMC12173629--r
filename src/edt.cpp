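#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared Euclidean distance transform of a sampled function f on a
// lattice with sample spacing w (Felzenszwalb & Huttenlocher lower
// envelope of parabolas). Sites with f = +Inf carry no parabola.
static void dt1d(const double* f, double* d, int n, double w,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = -1;
  double w2 = w * w;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; if (k < 0) break; } else break;
    }
    ++k; v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    double dq = w * (q - v[j]);
    d[q] = dq * dq + f[v[j]];
  }
}

// Squared Euclidean distance from every voxel centre to the nearest
// seed voxel centre, honouring anisotropic spacing. `mask` is a logical
// array in R's column-major layout with dimensions `dims` (length 3);
// `spacing` gives the physical sample spacing per axis in mm.
// Voxels with no seed anywhere map to +Inf.
// [[Rcpp::export(name = ".edt_squared")]]
NumericVector edt_squared(LogicalVector mask, IntegerVector dims,
                          NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  NumericVector out(n);
  double* g = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying)
  for (int kz = 0; kz < nz; ++kz)
    for (int ky = 0; ky < ny; ++ky) {
      double* row = g + (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
      dt1d(row, d.data(), nx, spacing[0], v, z);
      std::copy(d.begin(), d.begin() + nx, row);
    }
  // pass along y
  for (int kz = 0; kz < nz; ++kz)
    for (int kx = 0; kx < nx; ++kx) {
      double* base = g + (R_xlen_t)kz * nx * ny + kx;
      for (int ky = 0; ky < ny; ++ky) f[ky] = base[(R_xlen_t)ky * nx];
      dt1d(f.data(), d.data(), ny, spacing[1], v, z);
      for (int ky = 0; ky < ny; ++ky) base[(R_xlen_t)ky * nx] = d[ky];
    }
  // pass along z
  const R_xlen_t planes = (R_xlen_t)nx * ny;
  for (int ky = 0; ky < ny; ++ky)
    for (int kx = 0; kx < nx; ++kx) {
      double* base = g + (R_xlen_t)ky * nx + kx;
      for (int kz = 0; kz < nz; ++kz) f[kz] = base[kz * planes];
      dt1d(f.data(), d.data(), nz, spacing[2], v, z);
      for (int kz = 0; kz < nz; ++kz) base[kz * planes] = d[kz];
    }
  return out;
}

// Squared distance from query lattice points to the nearest seed point,
// both given as 0-based index triples on a common lattice with the given
// spacing. Seeds are scattered into a dense lattice of dimensions `dims`
// and transformed once; used for exact face-centre surface distances on
// a half-spacing lattice.
// [[Rcpp::export(name = ".edt_points")]]
NumericVector edt_points(IntegerMatrix seeds, IntegerMatrix queries,
                         IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector mark(n);
  for (int i = 0; i < seeds.nrow(); ++i) {
    R_xlen_t idx = (R_xlen_t)seeds(i, 2) * nx * ny +
                   (R_xlen_t)seeds(i, 1) * nx + seeds(i, 0);
    mark[idx] = true;
  }
  NumericVector dt = edt_squared(mark, dims, spacing);
  NumericVector out(queries.nrow());
  for (int i = 0; i < queries.nrow(); ++i) {
    R_xlen_t idx = (R_xlen_t)queries(i, 2) * nx * ny +
                   (R_xlen_t)queries(i, 1) * nx + queries(i, 0);
    out[i] = dt[idx];
  }
  return out;
}

// Separable 1D convolution along one axis of a 3D array (column-major),
// replicate padding at the edges. axis is 0, 1 or 2.
// [[Rcpp::export(name = ".convolve_axis3d")]]
NumericVector convolve_axis3d(NumericVector arr, IntegerVector dims,
                              NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (arr.size() != n) stop("array length does not match dims");
  const int klen = kernel.size();
  const int r = (klen - 1) / 2;
  NumericVector out(n);
  const double* src = REAL(arr);
  double* dst = REAL(out);
  const int len = dims[axis];
  R_xlen_t stride;
  if (axis == 0) stride = 1;
  else if (axis == 1) stride = nx;
  else stride = (R_xlen_t)nx * ny;
  std::vector<double> line(len);
  // iterate over all lines along `axis`
  const int na = dims[(axis + 1) % 3], nb = dims[(axis + 2) % 3];
  R_xlen_t sa, sb;
  if (axis == 0) { sa = nx; sb = (R_xlen_t)nx * ny; }
  else if (axis == 1) { sa = (R_xlen_t)nx * ny; sb = 1; }
  else { sa = 1; sb = nx; }
  for (int ib = 0; ib < nb; ++ib)
    for (int ia = 0; ia < na; ++ia) {
      const R_xlen_t base = ia * sa + ib * sb;
      for (int i = 0; i < len; ++i) line[i] = src[base + i * stride];
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int j = i + t;
          if (j < 0) j = 0; else if (j >= len) j = len - 1;
          acc += kernel[t + r] * line[j];
        }
        dst[base + i * stride] = acc;
      }
    }
  return out;
}
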