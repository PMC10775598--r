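#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 1D squared distance transform of a sampled function (Felzenszwalb &
// Huttenlocher 2012), with sample step h (mm). f holds squared distances.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double h, std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;  // index of rightmost parabola in the lower envelope
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;  // absent parabola, cannot support the envelope
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    for (;;) {
      double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * (xq - xv));
      if (s <= z[k]) {
        --k;
        if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; s = NA_REAL; break; }
      } else break;
    }
    if (!ISNA(s)) {
      ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
    }
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[j + 1] < xq) ++j;
    double dx = xq - v[j] * h;
    d[q] = dx * dx + f[v[j]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest set
// voxel centre of `mask`, with anisotropic spacing (z,y,x order matching
// the array dim). Unset-everywhere input yields Inf everywhere.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dims,
                     NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g((size_t)nz * ny * nx);
  for (size_t i = 0; i < g.size(); ++i) g[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z (fastest axis, stride 1)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      size_t base = (size_t)x * nz * ny + (size_t)y * nz;
      f.assign(g.begin() + base, g.begin() + base + nz);
      d.resize(nz);
      dt1d(f, d, spacing[0], v, z);
      for (int zi = 0; zi < nz; ++zi) g[base + zi] = d[zi];
    }
  // pass along y (stride nz)
  for (int x = 0; x < nx; ++x)
    for (int zi = 0; zi < nz; ++zi) {
      size_t base = (size_t)x * nz * ny + zi;
      f.resize(ny); d.resize(ny);
      for (int y = 0; y < ny; ++y) f[y] = g[base + (size_t)y * nz];
      dt1d(f, d, spacing[1], v, z);
      for (int y = 0; y < ny; ++y) g[base + (size_t)y * nz] = d[y];
    }
  // pass along x (stride nz*ny)
  for (int y = 0; y < ny; ++y)
    for (int zi = 0; zi < nz; ++zi) {
      size_t base = (size_t)y * nz + zi;
      f.resize(nx); d.resize(nx);
      for (int x = 0; x < nx; ++x) f[x] = g[base + (size_t)x * nz * ny];
      dt1d(f, d, spacing[2], v, z);
      for (int x = 0; x < nx; ++x) g[base + (size_t)x * nz * ny] = d[x];
    }

  NumericVector out((size_t)nz * ny * nx);
  for (size_t i = 0; i < g.size(); ++i) out[i] = g[i];
  out.attr("dim") = dims;
  return out;
}

// Trilinear sample of vol at continuous index positions (0-based, z/y/x).
// Out-of-grid samples contribute `fill` and are counted.
// [[Rcpp::export(name = ".trilinear_sample")]]
List trilinear_sample(NumericVector vol, IntegerVector dims,
                      NumericVector iz, NumericVector iy, NumericVector ix,
                      double fill) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const size_t n = iz.size();
  NumericVector out(n);
  int n_out = 0;
  auto at = [&](int z, int y, int x) {
    return vol[(size_t)x * nz * ny + (size_t)y * nz + z];
  };
  for (size_t i = 0; i < n; ++i) {
    double z = iz[i], y = iy[i], x = ix[i];
    if (z < 0 || y < 0 || x < 0 || z > nz - 1 || y > ny - 1 || x > nx - 1) {
      out[i] = fill; ++n_out; continue;
    }
    int z0 = (int)std::floor(z), y0 = (int)std::floor(y),
        x0 = (int)std::floor(x);
    if (z0 == nz - 1) --z0;
    if (y0 == ny - 1) --y0;
    if (x0 == nx - 1) --x0;
    if (nz == 1) z0 = 0;
    if (ny == 1) y0 = 0;
    if (nx == 1) x0 = 0;
    double fz = z - z0, fy = y - y0, fx = x - x0;
    int z1 = std::min(z0 + 1, nz - 1), y1 = std::min(y0 + 1, ny - 1),
        x1 = std::min(x0 + 1, nx - 1);
    double c00 = at(z0, y0, x0) * (1 - fz) + at(z1, y0, x0) * fz;
    double c10 = at(z0, y1, x0) * (1 - fz) + at(z1, y1, x0) * fz;
    double c01 = at(z0, y0, x1) * (1 - fz) + at(z1, y0, x1) * fz;
    double c11 = at(z0, y1, x1) * (1 - fz) + at(z1, y1, x1) * fz;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fx) + c1 * fx;
  }
  return List::create(_["values"] = out, _["n_outside"] = n_out);
}

// Separable Gaussian smoothing with per-axis sigma in voxel units and
// zero padding at the borders. Kernel truncated at 4 sigma.
// [[Rcpp::export(name = ".gauss_smooth")]]
NumericVector gauss_smooth(NumericVector vol, IntegerVector dims,
                           NumericVector sigma_vox) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  const int strides[3] = {1, nz, nz * ny};
  const int sizes[3] = {nz, ny, nx};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(4 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * i * i / (s * s));
      ksum += k[i + r];
    }
    for (double& kv : k) kv /= ksum;
    const int n = sizes[ax], st = strides[ax];
    const size_t total = a.size();
    for (size_t start = 0; start < total; ++start) {
      // iterate over lines along axis ax: positions whose index along ax is 0
      int idx_ax = (int)((start / st) % n);
      if (idx_ax != 0) continue;
      for (int p = 0; p < n; ++p) {
        double acc = 0;
        int lo = std::max(0, p - r), hi = std::min(n - 1, p + r);
        for (int q = lo; q <= hi; ++q)
          acc += a[start + (size_t)q * st] * k[q - p + r];
        b[start + (size_t)p * st] = acc;
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}
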