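#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---- 1-D squared distance transform (Felzenszwalb & Huttenlocher) ----
// f: sampled cost, out: lower envelope of parabolas rooted at (i, f[i]).
static void dt1d(const std::vector<double>& f, std::vector<double>& out) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
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
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double d = q - (double)v[k];
    out[q] = d * d + f[v[k]];
  }
}

// Squared Euclidean distance (in voxel units) from each TRUE voxel to the
// nearest FALSE voxel; 0 on FALSE voxels. Exact, separable in 3-D.
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double BIG = 1e18;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? BIG : 0.0;

  std::vector<double> f, g;
  // pass along x
  f.resize(nx); g.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = d[base + x];
      dt1d(f, g);
      for (int x = 0; x < nx; ++x) d[base + x] = g[x];
    }
  // pass along y
  f.resize(ny); g.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = d[base + (R_xlen_t)y * nx];
      dt1d(f, g);
      for (int y = 0; y < ny; ++y) d[base + (R_xlen_t)y * nx] = g[y];
    }
  // pass along z
  if (nz > 1) {
    f.resize(nz); g.resize(nz);
    const R_xlen_t stride = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; ++z) f[z] = d[base + (R_xlen_t)z * stride];
        dt1d(f, g);
        for (int z = 0; z < nz; ++z) d[base + (R_xlen_t)z * stride] = g[z];
      }
  }
  // cap unreplaced BIG (all-TRUE grid: distance undefined, report +Inf)
  for (R_xlen_t i = 0; i < n; ++i)
    if (d[i] >= BIG) d[i] = R_PosInf;
  return d;
}

// 6-connected components of TRUE voxels; 0 elsewhere, labels 1..k in
// decreasing order of discovery (relabelled by size on the R side).
// [[Rcpp::export(name = ".label6")]]
IntegerVector label6(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t i = q.front(); q.pop();
      int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / sz);
      R_xlen_t nb[6];
      int m = 0;
      if (x > 0)      nb[m++] = i - sx;
      if (x < nx - 1) nb[m++] = i + sx;
      if (y > 0)      nb[m++] = i - sy;
      if (y < ny - 1) nb[m++] = i + sy;
      if (z > 0)      nb[m++] = i - sz;
      if (z < nz - 1) nb[m++] = i + sz;
      for (int j = 0; j < m; ++j) {
        R_xlen_t t = nb[j];
        if (mask[t] && !lab[t]) { lab[t] = next; q.push(t); }
      }
    }
  }
  return lab;
}

// Local thickness (Hildebrand-Rueegsegger maximal-inscribed-sphere):
// thickness(p) = 2 * max{ r : p inside a sphere of radius r fully in mask }.
// Spheres are painted from the distance ridge (voxels whose inscribed sphere
// is not contained in a neighbour's sphere).
// [[Rcpp::export(name = ".local_thickness")]]
NumericVector local_thickness(LogicalVector mask, IntegerVector dim,
                              NumericVector edt_sq) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector th(n, 0.0);
  std::vector<double> r(n);
  for (R_xlen_t i = 0; i < n; ++i) r[i] = mask[i] ? std::sqrt(edt_sq[i]) : 0.0;

  const R_xlen_t sz = (R_xlen_t)nx * ny;
  // ridge: keep voxel p unless a 26-neighbour q has r_q >= r_p + |p-q|
  std::vector<R_xlen_t> ridge;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = (R_xlen_t)z * sz + (R_xlen_t)y * nx + x;
        if (!mask[i]) continue;
        bool redundant = false;
        for (int dz = -1; dz <= 1 && !redundant; ++dz)
          for (int dy = -1; dy <= 1 && !redundant; ++dy)
            for (int dx = -1; dx <= 1 && !redundant; ++dx) {
              if (!dx && !dy && !dz) continue;
              int X = x + dx, Y = y + dy, Z = z + dz;
              if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
                continue;
              R_xlen_t j = (R_xlen_t)Z * sz + (R_xlen_t)Y * nx + X;
              if (!mask[j]) continue;
              double dd = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
              if (r[j] >= r[i] + dd - 1e-9) redundant = true;
            }
        if (!redundant) ridge.push_back(i);
      }

  for (size_t k = 0; k < ridge.size(); ++k) {
    R_xlen_t i = ridge[k];
    double ri = r[i];
    double d2max = ri * ri + 1e-9;
    int R = (int)std::floor(ri + 1e-9);
    int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / sz);
    double tau = 2.0 * ri;
    for (int dz = -R; dz <= R; ++dz) {
      int Z = z + dz;
      if (Z < 0 || Z >= nz) continue;
      for (int dy = -R; dy <= R; ++dy) {
        int Y = y + dy;
        if (Y < 0 || Y >= ny) continue;
        double d2yz = (double)dz * dz + (double)dy * dy;
        if (d2yz > d2max) continue;
        int Rx = (int)std::floor(std::sqrt(d2max - d2yz));
        int x0 = x - Rx < 0 ? 0 : x - Rx;
        int x1 = x + Rx >= nx ? nx - 1 : x + Rx;
        R_xlen_t base = (R_xlen_t)Z * sz + (R_xlen_t)Y * nx;
        for (int X = x0; X <= x1; ++X) {
          R_xlen_t j = base + X;
          if (th[j] < tau) th[j] = tau;
        }
      }
    }
  }
  return th;
}
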