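#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 1-D squared-distance transform (lower envelope of parabolas) on a sampled
// line with physical spacing s.  f holds squared distances on input.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    while (true) {
      double xv = v[k] * s;
      double sep = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (sep <= z[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        z[k] = sep;
        z[k + 1] = std::numeric_limits<double>::infinity();
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// Exact Euclidean distance transform of a binary target on an anisotropic
// grid; returns distances in the same units as voxel_size (mm).
// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector target, IntegerVector dims,
                      NumericVector voxel_size) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::max() / 4;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = target[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = g[base + x];
      dt1d(f, d, nx, voxel_size[0]);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = g[base + (R_xlen_t)y * nx];
      dt1d(f, d, ny, voxel_size[1]);
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = g[base + (R_xlen_t)z * nx * ny];
      dt1d(f, d, nz, voxel_size[2]);
      for (int z = 0; z < nz; ++z) g[base + (R_xlen_t)z * nx * ny] = d[z];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}

static inline void neighbours6(int idx, int nx, int ny, int nz, int* nb,
                               int& cnt) {
  cnt = 0;
  int x = idx % nx, y = (idx / nx) % ny, z = idx / (nx * ny);
  if (x > 0)      nb[cnt++] = idx - 1;
  if (x < nx - 1) nb[cnt++] = idx + 1;
  if (y > 0)      nb[cnt++] = idx - nx;
  if (y < ny - 1) nb[cnt++] = idx + nx;
  if (z > 0)      nb[cnt++] = idx - nx * ny;
  if (z < nz - 1) nb[cnt++] = idx + nx * ny;
}

// Stochastic region growth from seed_idx (1-based): boundary voxels are
// accepted one at a time with probability proportional to field + eps,
// restricted to allowed, until n_target voxels.  Uses R's RNG.
// [[Rcpp::export(name = ".grow_lesion_cpp")]]
LogicalVector grow_lesion_cpp(NumericVector field, LogicalVector allowed,
                              IntegerVector dims, int seed_idx, int n_target) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const double eps = 1e-12;
  std::vector<char> state(n, 0);  // 0 outside, 1 in lesion, 2 candidate
  std::vector<int> cand;
  cand.reserve(1024);
  int nb[6], cnt;

  int cur = seed_idx - 1;
  state[cur] = 1;
  int grown = 1;
  neighbours6(cur, nx, ny, nz, nb, cnt);
  for (int k = 0; k < cnt; ++k)
    if (allowed[nb[k]] && state[nb[k]] == 0) {
      state[nb[k]] = 2;
      cand.push_back(nb[k]);
    }

  while (grown < n_target && !cand.empty()) {
    double tot = 0;
    for (size_t i = 0; i < cand.size(); ++i) tot += field[cand[i]] + eps;
    double u = unif_rand() * tot, acc = 0;
    size_t pick = cand.size() - 1;
    for (size_t i = 0; i < cand.size(); ++i) {
      acc += field[cand[i]] + eps;
      if (u <= acc) { pick = i; break; }
    }
    int v = cand[pick];
    cand[pick] = cand.back();
    cand.pop_back();
    state[v] = 1;
    ++grown;
    neighbours6(v, nx, ny, nz, nb, cnt);
    for (int k = 0; k < cnt; ++k)
      if (allowed[nb[k]] && state[nb[k]] == 0) {
        state[nb[k]] = 2;
        cand.push_back(nb[k]);
      }
  }

  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = state[i] == 1;
  out.attr("dim") = dims;
  return out;
}

// TRUE when all foreground voxels form one 6-connected component.
// [[Rcpp::export(name = ".connected6_cpp")]]
bool connected6_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  int total = 0, first = -1;
  for (int i = 0; i < n; ++i)
    if (mask[i]) { ++total; if (first < 0) first = i; }
  if (total == 0) return true;
  std::vector<char> seen(n, 0);
  std::queue<int> q;
  q.push(first);
  seen[first] = 1;
  int reached = 0, nb[6], cnt;
  while (!q.empty()) {
    int v = q.front(); q.pop();
    ++reached;
    neighbours6(v, nx, ny, nz, nb, cnt);
    for (int k = 0; k < cnt; ++k)
      if (mask[nb[k]] && !seen[nb[k]]) { seen[nb[k]] = 1; q.push(nb[k]); }
  }
  return reached == total;
}
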