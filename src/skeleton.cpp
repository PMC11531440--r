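// 3D curve skeletonization by sequential directional thinning of simple
// points (Bertrand-Malandain characterization: one 26-component of foreground
// in N26*, one 6-component of background in N18 touching the centre), and
// decomposition of the skeleton into branches between terminals.
//
// Lacuna voxels act as anchors: they count as foreground for the topology test
// but are never deleted, so canalicular branches stay attached to lacunae.
#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

namespace {

// cube index: (dx+1) + 3*(dy+1) + 9*(dz+1), centre = 13
int adj26[27][27];
int n26[27];
int adj6_18[27][27];
int n6_18[27];
bool in18[27];
bool face6[27];
bool tables_ready = false;

void build_tables() {
  if (tables_ready) return;
  for (int a = 0; a < 27; ++a) { // masks first: adjacency needs in18 for all b
    int ax = a % 3 - 1, ay = (a / 3) % 3 - 1, az = a / 9 - 1;
    int man = std::abs(ax) + std::abs(ay) + std::abs(az);
    in18[a] = (a != 13) && man <= 2;
    face6[a] = man == 1;
  }
  for (int a = 0; a < 27; ++a) {
    int ax = a % 3 - 1, ay = (a / 3) % 3 - 1, az = a / 9 - 1;
    n26[a] = 0;
    n6_18[a] = 0;
    for (int b = 0; b < 27; ++b) {
      if (a == b) continue;
      int bx = b % 3 - 1, by = (b / 3) % 3 - 1, bz = b / 9 - 1;
      int cx = std::abs(ax - bx), cy = std::abs(ay - by), cz = std::abs(az - bz);
      if (a != 13 && b != 13 && cx <= 1 && cy <= 1 && cz <= 1)
        adj26[a][n26[a]++] = b;
      if (in18[a] && in18[b] && cx + cy + cz == 1)
        adj6_18[a][n6_18[a]++] = b;
    }
  }
  tables_ready = true;
}

bool is_simple(const bool fg[27]) {
  // condition A: exactly one 26-component of foreground in N26*
  bool vis[27] = {false};
  int comps = 0;
  int stack[27];
  for (int a = 0; a < 27; ++a) {
    if (a == 13 || !fg[a] || vis[a]) continue;
    ++comps;
    if (comps > 1) return false;
    int top = 0;
    stack[top++] = a;
    vis[a] = true;
    while (top) {
      int cur = stack[--top];
      for (int t = 0; t < n26[cur]; ++t) {
        int b = adj26[cur][t];
        if (b != 13 && fg[b] && !vis[b]) {
          vis[b] = true;
          stack[top++] = b;
        }
      }
    }
  }
  if (comps != 1) return false;
  // condition B: exactly one 6-component of background in N18 touching centre
  bool visb[27] = {false};
  comps = 0;
  for (int a = 0; a < 27; ++a) {
    if (!in18[a] || fg[a] || visb[a] || !face6[a]) continue;
    // grow only components that contain a face neighbour
    ++comps;
    if (comps > 1) return false;
    int top = 0;
    stack[top++] = a;
    visb[a] = true;
    while (top) {
      int cur = stack[--top];
      for (int t = 0; t < n6_18[cur]; ++t) {
        int b = adj6_18[cur][t];
        if (!fg[b] && !visb[b]) {
          visb[b] = true;
          stack[top++] = b;
        }
      }
    }
  }
  return comps == 1;
}

} // namespace

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector canal, LogicalVector anchor,
                         IntegerVector dims) {
  build_tables();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> c(n), a(n);
  for (R_xlen_t i = 0; i < n; ++i) { c[i] = canal[i] ? 1 : 0; a[i] = anchor[i] ? 1 : 0; }

  // interleaved axis order: each axis is thinned from one side before any
  // axis sees its opposite side, which keeps 2-voxel ribbons from being
  // consumed lengthwise in a single pass
  const int dirs[6][3] = {{-1,0,0},{0,-1,0},{0,0,-1},{1,0,0},{0,1,0},{0,0,1}};
  auto fg_at = [&](int i, int j, int k) -> bool {
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return false;
    R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
    return c[v] || a[v];
  };

  // Each subiteration first collects the voxels that are border in its
  // direction, then deletes them sequentially with the simplicity and
  // endpoint conditions re-checked against the current state. Collecting
  // first is essential: otherwise a curve erodes end-to-end in one pass.
  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            if (!c[v]) continue;
            if (fg_at(i + dirs[d][0], j + dirs[d][1], k + dirs[d][2])) continue;
            cand.push_back(v);
          }
      for (R_xlen_t v : cand) {
        if (!c[v]) continue;
        int i = v % nx;
        int j = (v / nx) % ny;
        int k = v / ((R_xlen_t)nx * ny);
        bool fg[27];
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int idx = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
              bool f = (dx == 0 && dy == 0 && dz == 0)
                       ? true : fg_at(i + dx, j + dy, k + dz);
              fg[idx] = f;
              if (idx != 13 && f) ++cnt;
            }
        if (cnt <= 1) continue; // endpoint (or isolated): preserve
        if (is_simple(fg)) {
          c[v] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = c[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// Decompose a skeleton into branches between terminal voxels. Terminals are
// voxels with skeleton-neighbour count != 2 or voxels 26-adjacent to a lacuna
// voxel. Returns voxel paths (0-based i,j,k), end annotations
// (kind 0 = endpoint, 1 = junction cluster, 2 = lacuna; with id), junction
// cluster centroids, and the count of voxels in untraced pure cycles.
// [[Rcpp::export]]
List cpp_trace_branches(LogicalVector skel, IntegerVector lacuna,
                        IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;

  std::vector<R_xlen_t> voxels;
  for (R_xlen_t v = 0; v < n; ++v) if (skel[v]) voxels.push_back(v);

  std::vector<signed char> ncount(n, -1);
  std::vector<int> attach(n, 0);
  auto decode = [&](R_xlen_t v, int &i, int &j, int &k) {
    i = v % nx; j = (v / nx) % ny; k = v / ((R_xlen_t)nx * ny);
  };
  auto index = [&](int i, int j, int k) -> R_xlen_t {
    return i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  };

  for (R_xlen_t v : voxels) {
    int i, j, k;
    decode(v, i, j, k);
    int cnt = 0, att = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xi = i + dx, yj = j + dy, zk = k + dz;
          if (xi < 0 || xi >= nx || yj < 0 || yj >= ny || zk < 0 || zk >= nz) continue;
          R_xlen_t q = index(xi, yj, zk);
          if (skel[q]) ++cnt;
        }
    // attachment search in a 5x5x5 neighbourhood: thinning can leave branch
    // tips a voxel or two short of the reconstructed lacuna body
    for (int dz = -2; dz <= 2 && att == 0; ++dz)
      for (int dy = -2; dy <= 2 && att == 0; ++dy)
        for (int dx = -2; dx <= 2 && att == 0; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xi = i + dx, yj = j + dy, zk = k + dz;
          if (xi < 0 || xi >= nx || yj < 0 || yj >= ny || zk < 0 || zk >= nz) continue;
          R_xlen_t q = index(xi, yj, zk);
          if (lacuna[q] > 0) att = lacuna[q];
        }
    ncount[v] = (signed char)std::min(cnt, 127);
    attach[v] = att;
  }

  auto is_terminal = [&](R_xlen_t v) {
    return ncount[v] != 2 || attach[v] > 0;
  };

  // cluster junction voxels (terminal, no attachment, ncount >= 3)
  std::vector<int> cluster(n, 0);
  std::vector<double> csx, csy, csz;
  std::vector<int> csn;
  int ncl = 0;
  for (R_xlen_t v : voxels) {
    if (!(attach[v] == 0 && ncount[v] >= 3) || cluster[v] != 0) continue;
    ++ncl;
    csx.push_back(0); csy.push_back(0); csz.push_back(0); csn.push_back(0);
    std::vector<R_xlen_t> stack{v};
    cluster[v] = ncl;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i, j, k;
      decode(cur, i, j, k);
      csx[ncl - 1] += i; csy[ncl - 1] += j; csz[ncl - 1] += k; csn[ncl - 1] += 1;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xi = i + dx, yj = j + dy, zk = k + dz;
            if (xi < 0 || xi >= nx || yj < 0 || yj >= ny || zk < 0 || zk >= nz) continue;
            R_xlen_t q = index(xi, yj, zk);
            if (skel[q] && attach[q] == 0 && ncount[q] >= 3 && cluster[q] == 0) {
              cluster[q] = ncl;
              stack.push_back(q);
            }
          }
    }
  }

  auto end_kind = [&](R_xlen_t v) -> std::pair<int,int> {
    if (attach[v] > 0) return {2, attach[v]};
    if (ncount[v] >= 3) return {1, cluster[v]};
    return {0, 0};
  };

  std::vector<char> visited(n, 0);
  List paths;
  std::vector<int> ends_flat;
  long cyc = 0;

  std::vector<R_xlen_t> nb;
  auto neighbours = [&](R_xlen_t v, std::vector<R_xlen_t> &out) {
    out.clear();
    int i, j, k;
    decode(v, i, j, k);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xi = i + dx, yj = j + dy, zk = k + dz;
          if (xi < 0 || xi >= nx || yj < 0 || yj >= ny || zk < 0 || zk >= nz) continue;
          R_xlen_t q = index(xi, yj, zk);
          if (skel[q]) out.push_back(q);
        }
  };

  auto emit = [&](std::vector<R_xlen_t> &chain) {
    IntegerMatrix M((int)chain.size(), 3);
    for (size_t r = 0; r < chain.size(); ++r) {
      int i, j, k;
      decode(chain[r], i, j, k);
      M(r, 0) = i; M(r, 1) = j; M(r, 2) = k;
    }
    paths.push_back(M);
    auto e1 = end_kind(chain.front());
    auto e2 = end_kind(chain.back());
    ends_flat.push_back(e1.first); ends_flat.push_back(e1.second);
    ends_flat.push_back(e2.first); ends_flat.push_back(e2.second);
  };

  for (R_xlen_t t : voxels) {
    if (!is_terminal(t)) continue;
    neighbours(t, nb);
    std::vector<R_xlen_t> nbs = nb;
    for (R_xlen_t s : nbs) {
      if (is_terminal(s)) {
        if (t < s) {
          std::vector<R_xlen_t> chain{t, s};
          emit(chain);
        }
        continue;
      }
      if (visited[s]) continue;
      std::vector<R_xlen_t> chain{t, s};
      visited[s] = 1;
      R_xlen_t prev = t, cur = s;
      while (!is_terminal(cur)) {
        neighbours(cur, nb);
        R_xlen_t nxt = (R_xlen_t)-1;
        for (R_xlen_t q : nb) if (q != prev) { nxt = q; break; }
        if (nxt == (R_xlen_t)-1) break; // dangling interior (shouldn't happen)
        chain.push_back(nxt);
        if (!is_terminal(nxt)) visited[nxt] = 1;
        prev = cur;
        cur = nxt;
      }
      emit(chain);
    }
  }
  for (R_xlen_t v : voxels)
    if (!is_terminal(v) && !visited[v]) ++cyc; // pure cycles: dropped, counted

  int npaths = paths.size();
  IntegerMatrix ends(npaths, 4);
  for (int r = 0; r < npaths; ++r)
    for (int cix = 0; cix < 4; ++cix) ends(r, cix) = ends_flat[4 * r + cix];

  NumericMatrix cl(ncl, 4);
  for (int m = 0; m < ncl; ++m) {
    cl(m, 0) = csx[m] / csn[m];
    cl(m, 1) = csy[m] / csn[m];
    cl(m, 2) = csz[m] / csn[m];
    cl(m, 3) = csn[m];
  }
  return List::create(_["paths"] = paths, _["ends"] = ends,
                      _["clusters"] = cl, _["n_cycle_voxels"] = (double)cyc);
}
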