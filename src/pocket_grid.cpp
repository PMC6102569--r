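// Grid kernels for pocket detection: exact clearance field around the
// atoms, squared Euclidean distance transform (Felzenszwalb &
// Huttenlocher lower-envelope scan per axis), boundary-seeded flood fill
// and connected-component labelling, all on a regular 3D grid with
// 6-neighbour adjacency.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// large finite sentinel for "no source on this line" (squared cell
// distances in practice stay far below this)
static const double BIG = 1e15;

// clearance(x) = min over atoms of (|x - a_i| - r_i), clamped above at
// `cap` (values beyond cap are irrelevant downstream). Grid point g =
// origin + spacing * (ix, iy, iz), 0-based indices.
// [[Rcpp::export]]
NumericVector clearance_field(IntegerVector dim, NumericVector origin,
                              double spacing, NumericMatrix atoms,
                              NumericVector radii, double cap) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n, cap);
  const int na = atoms.nrow();
  for (int a = 0; a < na; ++a) {
    const double ax = atoms(a, 0), ay = atoms(a, 1), az = atoms(a, 2);
    const double r = radii[a];
    const double reach = r + cap;
    int ix0 = (int)std::ceil((ax - reach - origin[0]) / spacing);
    int ix1 = (int)std::floor((ax + reach - origin[0]) / spacing);
    int iy0 = (int)std::ceil((ay - reach - origin[1]) / spacing);
    int iy1 = (int)std::floor((ay + reach - origin[1]) / spacing);
    int iz0 = (int)std::ceil((az - reach - origin[2]) / spacing);
    int iz1 = (int)std::floor((az + reach - origin[2]) / spacing);
    if (ix0 < 0) ix0 = 0; if (ix1 >= nx) ix1 = nx - 1;
    if (iy0 < 0) iy0 = 0; if (iy1 >= ny) iy1 = ny - 1;
    if (iz0 < 0) iz0 = 0; if (iz1 >= nz) iz1 = nz - 1;
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double dz = origin[2] + spacing * iz - az;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = origin[1] + spacing * iy - ay;
        const double dyz2 = dy * dy + dz * dz;
        R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        for (int ix = ix0; ix <= ix1; ++ix) {
          const double dx = origin[0] + spacing * ix - ax;
          const double c = std::sqrt(dx * dx + dyz2) - r;
          if (c < out[base + ix]) out[base + ix] = c;
        }
      }
    }
  }
  return out;
}

// 1D squared distance transform (lower envelope of parabolas)
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// squared Euclidean distance (in cell units) from every grid point to the
// nearest TRUE cell of `mask`; INF when the mask is empty.
// [[Rcpp::export]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : BIG;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // along x
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      for (int ix = 0; ix < nx; ++ix) f[ix] = g[base + ix];
      dt1d(f, d, v, z, nx);
      for (int ix = 0; ix < nx; ++ix) g[base + ix] = d[ix];
    }
  // along y
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      R_xlen_t base = ix + (R_xlen_t)nx * ny * (R_xlen_t)iz;
      for (int iy = 0; iy < ny; ++iy) f[iy] = g[base + (R_xlen_t)nx * iy];
      dt1d(f, d, v, z, ny);
      for (int iy = 0; iy < ny; ++iy) g[base + (R_xlen_t)nx * iy] = d[iy];
    }
  // along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      R_xlen_t base = ix + (R_xlen_t)nx * iy;
      for (int iz = 0; iz < nz; ++iz) f[iz] = g[base + nxy * iz];
      dt1d(f, d, v, z, nz);
      for (int iz = 0; iz < nz; ++iz) g[base + nxy * iz] = d[iz];
    }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = g[i];
  return out;
}

// cells of `open` reachable from the box boundary via 6-neighbour steps
// [[Rcpp::export]]
LogicalVector flood_from_boundary(LogicalVector open, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector vis(n, false);
  std::vector<R_xlen_t> stack;
  stack.reserve(1 << 16);
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  auto push = [&](R_xlen_t id) {
    if (open[id] && !vis[id]) { vis[id] = true; stack.push_back(id); }
  };
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix)
        if (ix == 0 || iy == 0 || iz == 0 ||
            ix == nx - 1 || iy == ny - 1 || iz == nz - 1)
          push(ix + (R_xlen_t)nx * iy + nxy * iz);
  while (!stack.empty()) {
    R_xlen_t id = stack.back(); stack.pop_back();
    int iz = (int)(id / nxy);
    R_xlen_t rem = id - nxy * iz;
    int iy = (int)(rem / nx);
    int ix = (int)(rem - (R_xlen_t)nx * iy);
    if (ix > 0) push(id - 1);
    if (ix < nx - 1) push(id + 1);
    if (iy > 0) push(id - nx);
    if (iy < ny - 1) push(id + nx);
    if (iz > 0) push(id - nxy);
    if (iz < nz - 1) push(id + nxy);
  }
  return vis;
}

// 6-connected component labels (1-based; 0 outside the mask), in order of
// first appearance
// [[Rcpp::export]]
IntegerVector label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t id = stack.back(); stack.pop_back();
      int iz = (int)(id / nxy);
      R_xlen_t rem = id - nxy * iz;
      int iy = (int)(rem / nx);
      int ix = (int)(rem - (R_xlen_t)nx * iy);
      auto push = [&](R_xlen_t j) {
        if (mask[j] && !lab[j]) { lab[j] = cur; stack.push_back(j); }
      };
      if (ix > 0) push(id - 1);
      if (ix < nx - 1) push(id + 1);
      if (iy > 0) push(id - nx);
      if (iy < ny - 1) push(id + nx);
      if (iz > 0) push(id - nxy);
      if (iz < nz - 1) push(id + nxy);
    }
  }
  return lab;
}
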