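#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstring>
using namespace Rcpp;

static inline int vidx(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// ---- simple-point machinery (Bertrand's characterization) ----------------
// nb[27]: 3x3x3 neighborhood occupancy, index = (dx+1)+3*(dy+1)+9*(dz+1);
// center is index 13.

// number of 26-connected foreground components in N26 \ {p}
static int n26_components(const bool nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++ncomp;
    std::queue<int> q;
    q.push(s);
    seen[s] = true;
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
            int t = x + 3 * y + 9 * z;
            if (t == 13 || t == cur || seen[t] || !nb[t]) continue;
            seen[t] = true;
            q.push(t);
          }
    }
  }
  return ncomp;
}

static inline bool in_n18(int s) {
  int x = s % 3 - 1, y = (s / 3) % 3 - 1, z = s / 9 - 1;
  return (std::abs(x) + std::abs(y) + std::abs(z)) <= 2 && s != 13;
}

static inline bool is_n6(int s) {
  int x = s % 3 - 1, y = (s / 3) % 3 - 1, z = s / 9 - 1;
  return (std::abs(x) + std::abs(y) + std::abs(z)) == 1;
}

// number of 6-connected background components in N18 that touch a 6-neighbor
static int n6_bg_components(const bool nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (!is_n6(s) || nb[s] || seen[s]) continue;
    ++ncomp;
    std::queue<int> q;
    q.push(s);
    seen[s] = true;
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int d = 0; d < 6; ++d) {
        int x = cx + off[d][0], y = cy + off[d][1], z = cz + off[d][2];
        if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
        int t = x + 3 * y + 9 * z;
        if (t == 13 || seen[t] || nb[t] || !in_n18(t)) continue;
        seen[t] = true;
        q.push(t);
      }
    }
  }
  return ncomp;
}

static void fill_nb(const std::vector<char> &m, int i, int j, int k, int nx,
                    int ny, int nz, bool nb[27]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
        int x = i + dx, y = j + dy, z = k + dz;
        nb[s] = (x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz) &&
                m[vidx(x, y, z, nx, ny)] != 0;
      }
}

static inline bool is_simple(const std::vector<char> &m, int i, int j, int k,
                             int nx, int ny, int nz) {
  bool nb[27];
  fill_nb(m, i, j, k, nx, ny, nz, nb);
  return n26_components(nb) == 1 && n6_bg_components(nb) == 1;
}

static inline int n_fg_neighbors(const std::vector<char> &m, int i, int j,
                                 int k, int nx, int ny, int nz) {
  int cnt = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int x = i + dx, y = j + dy, z = k + dz;
        if (x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz &&
            m[vidx(x, y, z, nx, ny)])
          ++cnt;
      }
  return cnt;
}

// Endpoint/tip anchor: <= 1 neighbor, or exactly 2 mutually 26-adjacent
// neighbors (a "corner tip"). Without the second clause a two-voxel-wide
// ribbon unzips end to end during a sequential subiteration: the moving
// tip always keeps two adjacent neighbors, stays simple, and the branch
// retracts geometrically while remaining topologically correct.
static inline bool is_anchored_tip(const std::vector<char> &m, int i, int j,
                                   int k, int nx, int ny, int nz) {
  int cnt = 0;
  int px[2], py[2], pz[2];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int x = i + dx, y = j + dy, z = k + dz;
        if (x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz &&
            m[vidx(x, y, z, nx, ny)]) {
          if (cnt < 2) { px[cnt] = x; py[cnt] = y; pz[cnt] = z; }
          ++cnt;
        }
      }
  if (cnt <= 1) return true;
  if (cnt == 2) {
    return std::abs(px[0] - px[1]) <= 1 && std::abs(py[0] - py[1]) <= 1 &&
           std::abs(pz[0] - pz[1]) <= 1;
  }
  return false;
}

// 3D curve thinning: iterative directional (6-subiteration) removal of
// simple, non-endpoint border voxels until stable. Endpoint = exactly one
// foreground 26-neighbor.
// [[Rcpp::export]]
LogicalVector cpp_thin3(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> m(n);
  for (size_t t = 0; t < n; ++t) m[t] = mask[t] ? 1 : 0;
  const int dir[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  bool changed = true;
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            int id = vidx(i, j, k, nx, ny);
            if (!m[id]) continue;
            // border voxel in direction d (background neighbor there)
            int x = i + dir[d][0], y = j + dir[d][1], z = k + dir[d][2];
            bool bg = !(x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 &&
                        z < nz) ? false : (m[vidx(x, y, z, nx, ny)] == 0);
            if (!bg) continue;
            if (is_anchored_tip(m, i, j, k, nx, ny, nz)) continue;
            if (is_simple(m, i, j, k, nx, ny, nz)) cand.push_back(id);
          }
      // sequential re-check before deletion (parallel marking is unsafe)
      for (size_t t = 0; t < cand.size(); ++t) {
        int id = cand[t];
        int i = id % nx, j = (id / nx) % ny, k = id / (nx * ny);
        if (is_anchored_tip(m, i, j, k, nx, ny, nz)) continue;
        if (is_simple(m, i, j, k, nx, ny, nz)) {
          m[id] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(n);
  for (size_t t = 0; t < n; ++t) out[t] = m[t] != 0;
  out.attr("dim") = dim;
  return out;
}

// Connected-component labeling (connectivity 6 or 26), labels 1..K in
// first-voxel order, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label3(LogicalVector mask, IntegerVector dim,
                         int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  int next = 0;
  std::queue<int> q;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    q.push((int)s);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int i = cur % nx, j = (cur / nx) % ny, k = cur / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (connectivity == 6 && man != 1) continue;
            int x = i + dx, y = j + dy, z = k + dz;
            if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
              continue;
            int t = vidx(x, y, z, nx, ny);
            if (mask[t] && !lab[t]) {
              lab[t] = next;
              q.push(t);
            }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Edge list (1-based linear voxel indices, each unordered pair once) of the
// adjacency graph of foreground voxels.
// [[Rcpp::export]]
IntegerMatrix cpp_adjacency_pairs(LogicalVector mask, IntegerVector dim,
                                  int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<int> from, to;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    int i = s % nx, j = (s / nx) % ny, k = s / ((size_t)nx * ny);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
          if (connectivity == 6 && man != 1) continue;
          int x = i + dx, y = j + dy, z = k + dz;
          if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
            continue;
          size_t t = (size_t)vidx(x, y, z, nx, ny);
          if (t > s && mask[t]) {
            from.push_back((int)s + 1);
            to.push_back((int)t + 1);
          }
        }
  }
  IntegerMatrix out(from.size(), 2);
  for (size_t t = 0; t < from.size(); ++t) {
    out(t, 0) = from[t];
    out(t, 1) = to[t];
  }
  return out;
}

// ---- exact anisotropic Euclidean distance transform ----------------------
// Felzenszwalb & Huttenlocher 1D lower envelope, applied per axis on squared
// distances; spacing in um. Returns distance (um) to the nearest feature
// voxel.
static void dt1d(std::vector<double> &f, std::vector<double> &d, double h,
                 int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -1e300;
  z[1] = 1e300;
  double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e300;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = h2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3(LogicalVector feature, IntegerVector dim,
                       NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> g(n);
  for (size_t t = 0; t < n; ++t) g[t] = feature[t] ? 0.0 : 1e300;
  // x pass
  {
    std::vector<double> f(nx), d(nx);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) f[i] = g[vidx(i, j, k, nx, ny)];
        dt1d(f, d, spacing[0], nx);
        for (int i = 0; i < nx; ++i) g[vidx(i, j, k, nx, ny)] = d[i];
      }
  }
  // y pass
  {
    std::vector<double> f(ny), d(ny);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) f[j] = g[vidx(i, j, k, nx, ny)];
        dt1d(f, d, spacing[1], ny);
        for (int j = 0; j < ny; ++j) g[vidx(i, j, k, nx, ny)] = d[j];
      }
  }
  // z pass
  {
    std::vector<double> f(nz), d(nz);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k) f[k] = g[vidx(i, j, k, nx, ny)];
        dt1d(f, d, spacing[2], nz);
        for (int k = 0; k < nz; ++k) g[vidx(i, j, k, nx, ny)] = d[k];
      }
  }
  NumericVector out(n);
  for (size_t t = 0; t < n; ++t)
    out[t] = g[t] >= 1e299 ? R_PosInf : std::sqrt(g[t]);
  out.attr("dim") = dim;
  return out;
}
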