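// Greedy spatial stub matching for the synthetic network generator.
//
// Every node of the planned network exposes "stub sites" (junctions: k stubs
// at the node position; lacunae: one stub per surface anchor point). Sites are
// visited in a caller-supplied random order and paired with the available
// partner whose distance is closest to the target mean chord length d_star,
// subject to: maximum search radius, minimum length, no duplicate node pairs,
// no crossing of a forbidden interface plane, a minimum clearance between
// non-adjacent chords and around lacuna ellipsoids, and (softly) alignment
// with a preferred axis inside the ordered region. Unmatched stubs become
// dangling branches to free endpoints so that realized node degrees match the
// sampled ones. Fully deterministic given its inputs.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <array>
#include <cmath>
using namespace Rcpp;

namespace {

struct Seg {
  double a[3], b[3];
  int na, nb; // node ids (nb = -1 for dangling endpoint)
};

double seg_seg_d2(const double p1[3], const double q1[3],
                  const double p2[3], const double q2[3]) {
  // Ericson, Real-Time Collision Detection, closest point segment-segment
  double d1[3], d2[3], r[3];
  for (int i = 0; i < 3; ++i) {
    d1[i] = q1[i] - p1[i];
    d2[i] = q2[i] - p2[i];
    r[i] = p1[i] - p2[i];
  }
  double a = d1[0]*d1[0] + d1[1]*d1[1] + d1[2]*d1[2];
  double e = d2[0]*d2[0] + d2[1]*d2[1] + d2[2]*d2[2];
  double f = d2[0]*r[0] + d2[1]*r[1] + d2[2]*r[2];
  double s, t;
  const double EPS = 1e-12;
  if (a <= EPS && e <= EPS) { s = t = 0; }
  else if (a <= EPS) { s = 0; t = std::min(1.0, std::max(0.0, f / e)); }
  else {
    double c = d1[0]*r[0] + d1[1]*r[1] + d1[2]*r[2];
    if (e <= EPS) { t = 0; s = std::min(1.0, std::max(0.0, -c / a)); }
    else {
      double b = d1[0]*d2[0] + d1[1]*d2[1] + d1[2]*d2[2];
      double den = a * e - b * b;
      s = (den > EPS) ? std::min(1.0, std::max(0.0, (b * f - c * e) / den)) : 0.0;
      t = (b * s + f) / e;
      if (t < 0) { t = 0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1) { t = 1; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  double c1[3], c2[3];
  for (int i = 0; i < 3; ++i) {
    c1[i] = p1[i] + d1[i] * s;
    c2[i] = p2[i] + d2[i] * t;
  }
  double dx = c1[0]-c2[0], dy = c1[1]-c2[1], dz = c1[2]-c2[2];
  return dx*dx + dy*dy + dz*dz;
}

struct Grid {
  double cell;
  int gx, gy, gz;
  std::vector<std::vector<int>> bins;
  void init(const double dom[3], double c) {
    cell = std::max(c, 1e-6);
    gx = std::max(1, (int)std::ceil(dom[0] / cell));
    gy = std::max(1, (int)std::ceil(dom[1] / cell));
    gz = std::max(1, (int)std::ceil(dom[2] / cell));
    bins.assign((size_t)gx * gy * gz, {});
  }
  int clampi(int v, int hi) const { return v < 0 ? 0 : (v >= hi ? hi - 1 : v); }
  size_t at(double x, double y, double z) const {
    int i = clampi((int)(x / cell), gx), j = clampi((int)(y / cell), gy),
        k = clampi((int)(z / cell), gz);
    return (size_t)i + (size_t)gx * (j + (size_t)gy * k);
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_match_stubs(NumericMatrix site_pos, IntegerVector site_node,
                     LogicalVector site_aligned, IntegerVector site_ell,
                     NumericVector axis, double cos_tol,
                     double d_star, double r_max, double d_min,
                     double clearance,
                     NumericMatrix ell_centers, NumericMatrix ell_semi,
                     List ell_rot,
                     int iface_axis, double iface_pos,
                     IntegerVector order, NumericMatrix rand_dirs,
                     NumericVector domain) {
  const int m = site_pos.nrow();
  const int nell = ell_centers.nrow();
  double dom[3] = {domain[0], domain[1], domain[2]};

  std::vector<char> used(m, 0);
  Grid sites_grid;
  sites_grid.init(dom, std::max(r_max, 1.0));
  for (int s = 0; s < m; ++s)
    sites_grid.bins[sites_grid.at(site_pos(s,0), site_pos(s,1), site_pos(s,2))]
        .push_back(s);

  Grid seg_grid;
  seg_grid.init(dom, std::max(2.0 * clearance + d_star * 0.5, 2.0));
  std::vector<Seg> segs;

  // node pair dedup
  std::vector<std::vector<int>> partners;
  int nnodes = 0;
  for (int s = 0; s < m; ++s) nnodes = std::max(nnodes, site_node[s] + 1);
  partners.assign(nnodes, {});

  std::vector<NumericMatrix> rots(nell);
  for (int l = 0; l < nell; ++l) rots[l] = as<NumericMatrix>(ell_rot[l]);

  auto side_of = [&](const double p[3]) -> int {
    if (iface_axis < 0) return 0;
    return p[iface_axis] >= iface_pos ? 1 : -1;
  };

  auto in_ellipsoid = [&](const double p[3], int l) -> bool {
    const NumericMatrix &R = rots[l];
    double s0 = p[0] - ell_centers(l, 0), s1 = p[1] - ell_centers(l, 1),
           s2 = p[2] - ell_centers(l, 2);
    double d0 = R(0,0)*s0 + R(1,0)*s1 + R(2,0)*s2;
    double d1 = R(0,1)*s0 + R(1,1)*s1 + R(2,1)*s2;
    double d2 = R(0,2)*s0 + R(1,2)*s1 + R(2,2)*s2;
    double q = (d0/ell_semi(l,0))*(d0/ell_semi(l,0)) +
               (d1/ell_semi(l,1))*(d1/ell_semi(l,1)) +
               (d2/ell_semi(l,2))*(d2/ell_semi(l,2));
    return q <= 1.0;
  };

  // chord feasibility vs registered segments and ellipsoids
  auto chord_ok = [&](const double a[3], const double b[3],
                      int node_a, int node_b, int skip_ell_a, int skip_ell_b) -> bool {
    if (clearance > 0) {
      double lo[3], hi[3];
      for (int i = 0; i < 3; ++i) {
        lo[i] = std::min(a[i], b[i]) - clearance;
        hi[i] = std::max(a[i], b[i]) + clearance;
      }
      int i0 = seg_grid.clampi((int)(lo[0] / seg_grid.cell), seg_grid.gx);
      int i1 = seg_grid.clampi((int)(hi[0] / seg_grid.cell), seg_grid.gx);
      int j0 = seg_grid.clampi((int)(lo[1] / seg_grid.cell), seg_grid.gy);
      int j1 = seg_grid.clampi((int)(hi[1] / seg_grid.cell), seg_grid.gy);
      int k0 = seg_grid.clampi((int)(lo[2] / seg_grid.cell), seg_grid.gz);
      int k1 = seg_grid.clampi((int)(hi[2] / seg_grid.cell), seg_grid.gz);
      double cl2 = clearance * clearance;
      std::vector<int> seen;
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i)
            for (int sid : seg_grid.bins[(size_t)i + (size_t)seg_grid.gx *
                                         (j + (size_t)seg_grid.gy * k)]) {
              if (std::find(seen.begin(), seen.end(), sid) != seen.end()) continue;
              seen.push_back(sid);
              const Seg &sg = segs[sid];
              if (sg.na == node_a || sg.na == node_b ||
                  (sg.nb >= 0 && (sg.nb == node_a || sg.nb == node_b)))
                continue; // shares a node: allowed to meet
              if (seg_seg_d2(a, b, sg.a, sg.b) < cl2) return false;
            }
    }
    if (nell > 0) {
      double len = std::sqrt((b[0]-a[0])*(b[0]-a[0]) + (b[1]-a[1])*(b[1]-a[1]) +
                             (b[2]-a[2])*(b[2]-a[2]));
      int nsamp = std::max(2, (int)std::ceil(len / 0.25));
      for (int l = 0; l < nell; ++l) {
        if (l + 1 == skip_ell_a || l + 1 == skip_ell_b) continue;
        // bbox prefilter
        double rmax = std::max(ell_semi(l,0), std::max(ell_semi(l,1), ell_semi(l,2)));
        double cx = ell_centers(l,0), cy = ell_centers(l,1), cz = ell_centers(l,2);
        if (std::min(a[0], b[0]) > cx + rmax || std::max(a[0], b[0]) < cx - rmax ||
            std::min(a[1], b[1]) > cy + rmax || std::max(a[1], b[1]) < cy - rmax ||
            std::min(a[2], b[2]) > cz + rmax || std::max(a[2], b[2]) < cz - rmax)
          continue;
        for (int t = 0; t <= nsamp; ++t) {
          double u = (double)t / nsamp;
          double p[3] = {a[0] + u*(b[0]-a[0]), a[1] + u*(b[1]-a[1]),
                         a[2] + u*(b[2]-a[2])};
          if (in_ellipsoid(p, l)) return false;
        }
      }
    }
    return true;
  };

  auto register_seg = [&](const double a[3], const double b[3], int na, int nb) {
    Seg sg;
    for (int i = 0; i < 3; ++i) { sg.a[i] = a[i]; sg.b[i] = b[i]; }
    sg.na = na; sg.nb = nb;
    int sid = (int)segs.size();
    segs.push_back(sg);
    double pad = std::max(clearance, 0.5);
    int i0 = seg_grid.clampi((int)((std::min(a[0], b[0]) - pad) / seg_grid.cell), seg_grid.gx);
    int i1 = seg_grid.clampi((int)((std::max(a[0], b[0]) + pad) / seg_grid.cell), seg_grid.gx);
    int j0 = seg_grid.clampi((int)((std::min(a[1], b[1]) - pad) / seg_grid.cell), seg_grid.gy);
    int j1 = seg_grid.clampi((int)((std::max(a[1], b[1]) + pad) / seg_grid.cell), seg_grid.gy);
    int k0 = seg_grid.clampi((int)((std::min(a[2], b[2]) - pad) / seg_grid.cell), seg_grid.gz);
    int k1 = seg_grid.clampi((int)((std::max(a[2], b[2]) + pad) / seg_grid.cell), seg_grid.gz);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          seg_grid.bins[(size_t)i + (size_t)seg_grid.gx * (j + (size_t)seg_grid.gy * k)]
              .push_back(sid);
  };

  std::vector<int> e_from, e_to;
  std::vector<int> dang_site;
  std::vector<double> dang_x, dang_y, dang_z;

  const int MAX_TRY = 40;

  for (int oi = 0; oi < m; ++oi) {
    int s = order[oi];
    if (used[s]) continue;
    double ps[3] = {site_pos(s,0), site_pos(s,1), site_pos(s,2)};
    int ns = site_node[s];
    int sidec = side_of(ps);

    // gather candidates
    std::vector<std::pair<double,int>> cand; // (score, site)
    int bi = sites_grid.clampi((int)(ps[0] / sites_grid.cell), sites_grid.gx);
    int bj = sites_grid.clampi((int)(ps[1] / sites_grid.cell), sites_grid.gy);
    int bk = sites_grid.clampi((int)(ps[2] / sites_grid.cell), sites_grid.gz);
    for (int k = std::max(0, bk-1); k <= std::min(sites_grid.gz-1, bk+1); ++k)
      for (int j = std::max(0, bj-1); j <= std::min(sites_grid.gy-1, bj+1); ++j)
        for (int i = std::max(0, bi-1); i <= std::min(sites_grid.gx-1, bi+1); ++i)
          for (int u : sites_grid.bins[(size_t)i + (size_t)sites_grid.gx *
                                       (j + (size_t)sites_grid.gy * k)]) {
            if (used[u] || u == s) continue;
            int nu = site_node[u];
            if (nu == ns) continue;
            double pu[3] = {site_pos(u,0), site_pos(u,1), site_pos(u,2)};
            double dx = pu[0]-ps[0], dy = pu[1]-ps[1], dz = pu[2]-ps[2];
            double d = std::sqrt(dx*dx + dy*dy + dz*dz);
            if (d > r_max || d < d_min) continue;
            if (iface_axis >= 0 && side_of(pu) != sidec) continue;
            if (std::find(partners[ns].begin(), partners[ns].end(), nu) !=
                partners[ns].end())
              continue;
            double score = std::fabs(d - d_star);
            if (site_aligned[s] && site_aligned[u]) {
              // ordered region: prefer in-cone partners whenever one is
              // available; partner scarcity under the clearance and
              // hard-core constraints makes a hard cone infeasible
              double ca = std::fabs((dx*axis[0] + dy*axis[1] + dz*axis[2]) / d);
              if (ca < cos_tol) score += 1e3;
            }
            cand.push_back({score, u});
          }
    std::sort(cand.begin(), cand.end());

    bool matched = false;
    int tries = std::min((int)cand.size(), MAX_TRY);
    for (int t = 0; t < tries; ++t) {
      int u = cand[t].second;
      double pu[3] = {site_pos(u,0), site_pos(u,1), site_pos(u,2)};
      if (!chord_ok(ps, pu, ns, site_node[u], site_ell[s], site_ell[u])) continue;
      used[s] = used[u] = 1;
      partners[ns].push_back(site_node[u]);
      partners[site_node[u]].push_back(ns);
      register_seg(ps, pu, ns, site_node[u]);
      e_from.push_back(s);
      e_to.push_back(u);
      matched = true;
      break;
    }
    if (matched) continue;

    // dangling branch: keep the sampled degree by adding a free endpoint
    double rd[3] = {rand_dirs(s,0), rand_dirs(s,1), rand_dirs(s,2)};
    std::vector<std::array<double,3>> dirs;
    if (site_ell[s] > 0) {
      // lacuna stub: outward normal first, then tilted variants
      double ax2[3] = {0.8 * rd[0] + 0.6 * axis[0], 0.8 * rd[1] + 0.6 * axis[1],
                       0.8 * rd[2] + 0.6 * axis[2]};
      double n2 = std::sqrt(ax2[0]*ax2[0] + ax2[1]*ax2[1] + ax2[2]*ax2[2]);
      if (n2 < 1e-9) { ax2[0] = rd[1]; ax2[1] = rd[2]; ax2[2] = rd[0]; n2 = 1; }
      double ax3[3] = {0.8 * rd[0] - 0.6 * axis[0], 0.8 * rd[1] - 0.6 * axis[1],
                       0.8 * rd[2] - 0.6 * axis[2]};
      double n3 = std::sqrt(ax3[0]*ax3[0] + ax3[1]*ax3[1] + ax3[2]*ax3[2]);
      if (n3 < 1e-9) { ax3[0] = rd[2]; ax3[1] = rd[0]; ax3[2] = rd[1]; n3 = 1; }
      dirs = {{rd[0], rd[1], rd[2]},
              {ax2[0] / n2, ax2[1] / n2, ax2[2] / n2},
              {ax3[0] / n3, ax3[1] / n3, ax3[2] / n3}};
    } else if (site_aligned[s]) {
      dirs = {{axis[0], axis[1], axis[2]},
              {-axis[0], -axis[1], -axis[2]},
              {rd[0], rd[1], rd[2]},
              {-rd[0], -rd[1], -rd[2]}};
    } else {
      dirs = {{rd[0], rd[1], rd[2]},
              {-rd[0], -rd[1], -rd[2]},
              {axis[0], axis[1], axis[2]}};
    }
    for (auto &dv : dirs) {
      double ep[3] = {ps[0] + d_star * dv[0], ps[1] + d_star * dv[1],
                      ps[2] + d_star * dv[2]};
      bool inside = true;
      for (int i = 0; i < 3; ++i)
        if (ep[i] < 0.1 || ep[i] > dom[i] - 0.1) inside = false;
      if (!inside) continue;
      if (iface_axis >= 0 && side_of(ep) != sidec) continue;
      if (!chord_ok(ps, ep, ns, -1, site_ell[s], 0)) continue;
      used[s] = 1;
      register_seg(ps, ep, ns, -1);
      dang_site.push_back(s);
      dang_x.push_back(ep[0]); dang_y.push_back(ep[1]); dang_z.push_back(ep[2]);
      break;
    }
  }

  IntegerMatrix edges((int)e_from.size(), 2);
  for (int r = 0; r < (int)e_from.size(); ++r) {
    edges(r, 0) = e_from[r];
    edges(r, 1) = e_to[r];
  }
  int nd = (int)dang_site.size();
  NumericMatrix dend(nd, 3);
  IntegerVector dsite(nd);
  for (int r = 0; r < nd; ++r) {
    dsite[r] = dang_site[r];
    dend(r, 0) = dang_x[r]; dend(r, 1) = dang_y[r]; dend(r, 2) = dang_z[r];
  }
  LogicalVector usedv(m);
  for (int s = 0; s < m; ++s) usedv[s] = used[s] != 0;
  return List::create(_["edges"] = edges, _["dangling_site"] = dsite,
                      _["dangling_end"] = dend, _["used"] = usedv);
}
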