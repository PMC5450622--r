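// Low-level voxel algorithms shared by the mesh, skeleton and session modules.
// Array layout follows R: column-major with dim = (M rows = y, N cols = x, Z slices).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline R_xlen_t idx3(int y, int x, int z, int M, int N) {
  return (R_xlen_t)y + (R_xlen_t)M * ((R_xlen_t)x + (R_xlen_t)N * (R_xlen_t)z);
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on a scalar field.
//
// Each grid cell is split into the six Kuhn tetrahedra along its main
// diagonal; the split is identical in every cell, so shared cell faces carry
// the same diagonal and the extracted surface is watertight. Surface vertices
// lie on grid edges (linear interpolation to the iso-level) and are shared via
// an edge-keyed map. Triangles are oriented with outward normals (away from
// the > level side), so signed volumes accumulate consistently.
// ---------------------------------------------------------------------------

// The six axis-order permutations defining the Kuhn subdivision. Corners are
// encoded as (cx, cy, cz) offsets; each tet is 000 -> e_a -> e_a+e_b -> 111.
static const int TET_PERMS[6][3] = {
  {0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}
};

struct VKey {
  uint64_t a, b;
};

// [[Rcpp::export(name = ".mtMarch")]]
List mtMarch(NumericVector field, double level) {
  IntegerVector dm = field.attr("dim");
  if (dm.size() != 3) stop("field must be a 3D array");
  const int M = dm[0], N = dm[1], Z = dm[2];
  const double *F = REAL(field);

  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;

  // global node id for hashing
  auto nid = [&](int y, int x, int z) -> uint64_t {
    return (uint64_t)idx3(y, x, z, M, N);
  };

  int cy[8], cx[8], cz[8];

  auto vertex_on_edge = [&](uint64_t n0, uint64_t n1) -> int {
    uint64_t lo = n0 < n1 ? n0 : n1, hi = n0 < n1 ? n1 : n0;
    uint64_t key = lo * (uint64_t)(M * (R_xlen_t)N * Z + 1) + hi;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    // decode node -> (y,x,z)
    auto dec = [&](uint64_t n, int &y, int &x, int &z) {
      y = (int)(n % M); n /= M; x = (int)(n % N); z = (int)(n / N);
    };
    int y0, x0, z0, y1, x1, z1;
    dec(lo, y0, x0, z0); dec(hi, y1, x1, z1);
    double f0 = F[lo], f1 = F[hi];
    double t = (level - f0) / (f1 - f0);
    vx.push_back(x0 + t * (x1 - x0));
    vy.push_back(y0 + t * (y1 - y0));
    vz.push_back(z0 + t * (z1 - z0));
    int id = (int)vx.size() - 1;
    vmap.emplace(key, id);
    return id;
  };

  auto emit = [&](int i0, int i1, int i2, const double *pin, const double *pout) {
    // orient so the normal points from inside (> level) to outside
    double ux = vx[i1] - vx[i0], uy = vy[i1] - vy[i0], uz = vz[i1] - vz[i0];
    double wx2 = vx[i2] - vx[i0], wy2 = vy[i2] - vy[i0], wz2 = vz[i2] - vz[i0];
    double nx = uy * wz2 - uz * wy2;
    double ny = uz * wx2 - ux * wz2;
    double nz = ux * wy2 - uy * wx2;
    double dx = pout[0] - pin[0], dy = pout[1] - pin[1], dz = pout[2] - pin[2];
    if (nx * dx + ny * dy + nz * dz < 0) { int t = i1; i1 = i2; i2 = t; }
    fa.push_back(i0 + 1); fb.push_back(i1 + 1); fc.push_back(i2 + 1);
  };

  for (int z = 0; z + 1 < Z; ++z)
    for (int x = 0; x + 1 < N; ++x)
      for (int y = 0; y + 1 < M; ++y) {
        uint64_t node[8];
        double val[8];
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          cx[c] = c & 1; cy[c] = (c >> 1) & 1; cz[c] = (c >> 2) & 1;
          node[c] = nid(y + cy[c], x + cx[c], z + cz[c]);
          val[c] = F[node[c]];
          if (val[c] > level) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int p = 0; p < 6; ++p) {
          // corner bit per axis: axis 0 = x, 1 = y, 2 = z
          int a = TET_PERMS[p][0], b = TET_PERMS[p][1];
          int c0 = 0;
          int c1 = 1 << a;          // bit order: x bit0, y bit1, z bit2
          int c2 = c1 | (1 << b);
          int c3 = 7;
          int tc[4] = {c0, c1, c2, c3};
          bool in[4];
          int nin = 0;
          for (int k = 0; k < 4; ++k) { in[k] = val[tc[k]] > level; nin += in[k]; }
          if (nin == 0 || nin == 4) continue;
          // representative inside/outside corner positions (grid coords)
          double pin[3] = {0, 0, 0}, pout[3] = {0, 0, 0};
          for (int k = 0; k < 4; ++k) {
            double px = x + cx[tc[k]], py = y + cy[tc[k]], pz = z + cz[tc[k]];
            if (in[k]) { pin[0] = px; pin[1] = py; pin[2] = pz; }
            else { pout[0] = px; pout[1] = py; pout[2] = pz; }
          }
          if (nin == 1 || nin == 3) {
            int lone = -1;
            for (int k = 0; k < 4; ++k) if (in[k] == (nin == 1)) lone = k;
            int vids[3]; int j = 0;
            for (int k = 0; k < 4; ++k) if (k != lone)
              vids[j++] = vertex_on_edge(node[tc[lone]], node[tc[k]]);
            emit(vids[0], vids[1], vids[2], pin, pout);
          } else {
            int ia[2], oa[2], ji = 0, jo = 0;
            for (int k = 0; k < 4; ++k) { if (in[k]) ia[ji++] = k; else oa[jo++] = k; }
            int q0 = vertex_on_edge(node[tc[ia[0]]], node[tc[oa[0]]]);
            int q1 = vertex_on_edge(node[tc[ia[0]]], node[tc[oa[1]]]);
            int q2 = vertex_on_edge(node[tc[ia[1]]], node[tc[oa[1]]]);
            int q3 = vertex_on_edge(node[tc[ia[1]]], node[tc[oa[0]]]);
            emit(q0, q1, q2, pin, pout);
            emit(q0, q2, q3, pin, pout);
          }
        }
      }

  int nv = (int)vx.size(), nf = (int)fa.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix Fc(nf, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i]; }
  for (int i = 0; i < nf; ++i) { Fc(i, 0) = fa[i]; Fc(i, 1) = fb[i]; Fc(i, 2) = fc[i]; }
  return List::create(_["vertices"] = V, _["faces"] = Fc);
}

// ---------------------------------------------------------------------------
// Simple-point test (26-connectivity for foreground, 6 for background) and
// sequential topology-preserving thinning with curve-endpoint preservation.
// ---------------------------------------------------------------------------

// offsets of the 26-neighborhood, index 0..25
static int NB26[26][3]; static bool NB26_init = false;
static void init_nb26() {
  if (NB26_init) return;
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        NB26[k][0] = dy; NB26[k][1] = dx; NB26[k][2] = dz; ++k;
      }
  NB26_init = true;
}

// foreground flags for the 26 neighbors of a voxel (outside = background)
static void fetch_nbhd(const int *mask, int y, int x, int z, int M, int N, int Z,
                       bool fg[26]) {
  for (int k = 0; k < 26; ++k) {
    int yy = y + NB26[k][0], xx = x + NB26[k][1], zz = z + NB26[k][2];
    fg[k] = (yy >= 0 && yy < M && xx >= 0 && xx < N && zz >= 0 && zz < Z)
      ? mask[idx3(yy, xx, zz, M, N)] != 0 : false;
  }
}

static int n26_fg(const bool fg[26]) {
  int n = 0;
  for (int k = 0; k < 26; ++k) n += fg[k];
  return n;
}

// number of 26-connected components among foreground neighbors
static int cc26(const bool fg[26]) {
  bool seen[26] = {false};
  int ncomp = 0;
  for (int s = 0; s < 26; ++s) {
    if (!fg[s] || seen[s]) continue;
    ++ncomp;
    std::vector<int> stack(1, s);
    seen[s] = true;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (int v = 0; v < 26; ++v) {
        if (!fg[v] || seen[v]) continue;
        if (std::abs(NB26[u][0] - NB26[v][0]) <= 1 &&
            std::abs(NB26[u][1] - NB26[v][1]) <= 1 &&
            std::abs(NB26[u][2] - NB26[v][2]) <= 1) {
          seen[v] = true; stack.push_back(v);
        }
      }
    }
  }
  return ncomp;
}

// number of 6-connected background components within the 18-neighborhood that
// touch a face neighbor of the center
static int cc6_bg18(const bool fg[26]) {
  bool in18[26], bg[26], seen[26] = {false};
  for (int k = 0; k < 26; ++k) {
    int m = std::abs(NB26[k][0]) + std::abs(NB26[k][1]) + std::abs(NB26[k][2]);
    in18[k] = (m <= 2);
    bg[k] = !fg[k];
  }
  int ncomp = 0;
  for (int s = 0; s < 26; ++s) {
    int ms = std::abs(NB26[s][0]) + std::abs(NB26[s][1]) + std::abs(NB26[s][2]);
    if (ms != 1 || !bg[s] || seen[s]) continue;   // seed only at face neighbors
    ++ncomp;
    std::vector<int> stack(1, s);
    seen[s] = true;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (int v = 0; v < 26; ++v) {
        if (!in18[v] || !bg[v] || seen[v]) continue;
        int d = std::abs(NB26[u][0] - NB26[v][0]) + std::abs(NB26[u][1] - NB26[v][1]) +
                std::abs(NB26[u][2] - NB26[v][2]);
        if (d == 1) { seen[v] = true; stack.push_back(v); }
      }
    }
  }
  return ncomp;
}

static bool is_simple(const int *mask, int y, int x, int z, int M, int N, int Z) {
  bool fg[26];
  fetch_nbhd(mask, y, x, z, M, N, Z, fg);
  if (n26_fg(fg) == 0) return false;      // isolated voxel: never delete
  return cc26(fg) == 1 && cc6_bg18(fg) == 1;
}

static bool is_endpoint(const int *mask, int y, int x, int z, int M, int N, int Z) {
  bool fg[26];
  fetch_nbhd(mask, y, x, z, M, N, Z, fg);
  return n26_fg(fg) <= 1;
}

// [[Rcpp::export(name = ".thin3d")]]
LogicalVector thin3d(LogicalVector mask) {
  init_nb26();
  IntegerVector dm = mask.attr("dim");
  if (dm.size() != 3) stop("mask must be a 3D array");
  const int M = dm[0], N = dm[1], Z = dm[2];
  LogicalVector out = clone(mask);
  int *m = LOGICAL(out);
  // the six face directions, applied in turn (dy, dx, dz)
  static const int DIRS[6][3] = {
    {0,0,-1},{0,0,1},{-1,0,0},{1,0,0},{0,-1,0},{0,1,0}
  };
  bool changed = true;
  std::vector<R_xlen_t> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < Z; ++z)
        for (int x = 0; x < N; ++x)
          for (int y = 0; y < M; ++y) {
            R_xlen_t i = idx3(y, x, z, M, N);
            if (!m[i]) continue;
            int yy = y + DIRS[d][0], xx = x + DIRS[d][1], zz = z + DIRS[d][2];
            bool borderBg = !(yy >= 0 && yy < M && xx >= 0 && xx < N &&
                              zz >= 0 && zz < Z) ||
                            !m[idx3(yy, xx, zz, M, N)];
            if (!borderBg) continue;
            if (is_endpoint(m, y, x, z, M, N, Z)) continue;
            if (is_simple(m, y, x, z, M, N, Z)) cand.push_back(i);
          }
      // sequential re-checked deletion keeps topology exact
      for (R_xlen_t i : cand) {
        int y = (int)(i % M), x = (int)((i / M) % N), z = (int)(i / ((R_xlen_t)M * N));
        if (!m[i]) continue;
        if (is_endpoint(m, y, x, z, M, N, Z)) continue;
        if (is_simple(m, y, x, z, M, N, Z)) { m[i] = 0; changed = true; }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Anisotropic squared Euclidean distance transform (Felzenszwalb-Huttenlocher
// separable lower-envelope method). Distance from each true voxel to the
// nearest false voxel center; the volume border counts as background.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double> &f, std::vector<double> &d, double w2, int n) {
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0; zb[0] = -INFINITY; zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; zb[k] = s; zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3dSq")]]
NumericVector edt3dSq(LogicalVector mask, double dy, double dx, double dz) {
  IntegerVector dm = mask.attr("dim");
  if (dm.size() != 3) stop("mask must be a 3D array");
  const int M = dm[0], N = dm[1], Z = dm[2];
  const int *m = LOGICAL(mask);
  NumericVector out(mask.size());
  double *o = REAL(out);
  const double INF = 1e300;
  for (R_xlen_t i = 0; i < mask.size(); ++i) o[i] = m[i] ? INF : 0.0;

  std::vector<double> f, d;
  // pass along y
  f.resize(M); d.resize(M);
  for (int z = 0; z < Z; ++z)
    for (int x = 0; x < N; ++x) {
      for (int y = 0; y < M; ++y) f[y] = o[idx3(y, x, z, M, N)];
      dt1d(f, d, dy * dy, M);
      for (int y = 0; y < M; ++y) o[idx3(y, x, z, M, N)] = d[y];
    }
  // pass along x
  f.resize(N); d.resize(N);
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < M; ++y) {
      for (int x = 0; x < N; ++x) f[x] = o[idx3(y, x, z, M, N)];
      dt1d(f, d, dx * dx, N);
      for (int x = 0; x < N; ++x) o[idx3(y, x, z, M, N)] = d[x];
    }
  // pass along z
  f.resize(Z); d.resize(Z);
  for (int y = 0; y < M; ++y)
    for (int x = 0; x < N; ++x) {
      for (int z = 0; z < Z; ++z) f[z] = o[idx3(y, x, z, M, N)];
      dt1d(f, d, dz * dz, Z);
      for (int z = 0; z < Z; ++z) o[idx3(y, x, z, M, N)] = d[z];
    }
  // volume border is background: nearest outside voxel center is axis-aligned
  for (int z = 0; z < Z; ++z)
    for (int x = 0; x < N; ++x)
      for (int y = 0; y < M; ++y) {
        R_xlen_t i = idx3(y, x, z, M, N);
        if (!m[i]) continue;
        double b = dy * (y + 1); b = std::min(b, dy * (M - y));
        b = std::min(b, dx * (x + 1)); b = std::min(b, dx * (N - x));
        b = std::min(b, dz * (z + 1)); b = std::min(b, dz * (Z - z));
        o[i] = std::min(o[i], b * b);
      }
  out.attr("dim") = dm;
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling: 8-connectivity on a 2D slice, 26 in 3D.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".label2d8")]]
IntegerMatrix label2d8(LogicalMatrix mask) {
  const int M = mask.nrow(), N = mask.ncol();
  IntegerMatrix lab(M, N);
  int next = 0;
  std::vector<std::pair<int,int> > stack;
  for (int x = 0; x < N; ++x)
    for (int y = 0; y < M; ++y) {
      if (!mask(y, x) || lab(y, x)) continue;
      ++next;
      stack.clear(); stack.push_back(std::make_pair(y, x));
      lab(y, x) = next;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back(); stack.pop_back();
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int yy = p.first + dy, xx = p.second + dx;
            if (yy < 0 || yy >= M || xx < 0 || xx >= N) continue;
            if (mask(yy, xx) && !lab(yy, xx)) {
              lab(yy, xx) = next;
              stack.push_back(std::make_pair(yy, xx));
            }
          }
      }
    }
  return lab;
}

// [[Rcpp::export(name = ".label3d26")]]
IntegerVector label3d26(LogicalVector mask) {
  init_nb26();
  IntegerVector dm = mask.attr("dim");
  if (dm.size() != 3) stop("mask must be a 3D array");
  const int M = dm[0], N = dm[1], Z = dm[2];
  const int *m = LOGICAL(mask);
  IntegerVector lab(mask.size());
  int *L = INTEGER(lab);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    if (!m[i] || L[i]) continue;
    ++next;
    stack.clear(); stack.push_back(i);
    L[i] = next;
    while (!stack.empty()) {
      R_xlen_t u = stack.back(); stack.pop_back();
      int y = (int)(u % M), x = (int)((u / M) % N), z = (int)(u / ((R_xlen_t)M * N));
      for (int k = 0; k < 26; ++k) {
        int yy = y + NB26[k][0], xx = x + NB26[k][1], zz = z + NB26[k][2];
        if (yy < 0 || yy >= M || xx < 0 || xx >= N || zz < 0 || zz >= Z) continue;
        R_xlen_t v = idx3(yy, xx, zz, M, N);
        if (m[v] && !L[v]) { L[v] = next; stack.push_back(v); }
      }
    }
  }
  lab.attr("dim") = dm;
  return lab;
}
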