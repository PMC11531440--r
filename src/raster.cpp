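// Voxelization of the synthetic ground truth: tubes along polyline paths and
// oriented ellipsoids, both via supersampled inside tests (3x3x3 subsamples
// per voxel), plus exact clipping of polyline segments to a cubic cell grid.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline double clamp01(double t) {
  return t < 0 ? 0 : (t > 1 ? 1 : t);
}

// squared distance from point to segment [p,q]
static double pt_seg_d2(double x, double y, double z,
                        double px, double py, double pz,
                        double qx, double qy, double qz) {
  double vx = qx - px, vy = qy - py, vz = qz - pz;
  double wx = x - px, wy = y - py, wz = z - pz;
  double vv = vx * vx + vy * vy + vz * vz;
  double t = (vv > 0) ? clamp01((wx * vx + wy * vy + wz * vz) / vv) : 0.0;
  double dx = wx - t * vx, dy = wy - t * vy, dz = wz - t * vz;
  return dx * dx + dy * dy + dz * dz;
}

// paths: list of (n x 3) matrices in um. Accumulates, per voxel, the maximum
// fraction of 27 subsamples lying within `radius` of any path.
// [[Rcpp::export]]
NumericVector cpp_raster_tubes(List paths, double radius,
                               IntegerVector dims, NumericVector spacing,
                               NumericVector img) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double wx = spacing[0], wy = spacing[1], wz = spacing[2];
  const int ss = 3;
  const double inv = 1.0 / (ss * ss * ss);

  for (int e = 0; e < paths.size(); ++e) {
    NumericMatrix P = paths[e];
    for (int s = 0; s + 1 < P.nrow(); ++s) {
      double px = P(s, 0), py = P(s, 1), pz = P(s, 2);
      double qx = P(s + 1, 0), qy = P(s + 1, 1), qz = P(s + 1, 2);
      int i0 = std::max(0, (int)std::floor((std::min(px, qx) - radius) / wx) - 1);
      int i1 = std::min(nx - 1, (int)std::ceil((std::max(px, qx) + radius) / wx) + 1);
      int j0 = std::max(0, (int)std::floor((std::min(py, qy) - radius) / wy) - 1);
      int j1 = std::min(ny - 1, (int)std::ceil((std::max(py, qy) + radius) / wy) + 1);
      int k0 = std::max(0, (int)std::floor((std::min(pz, qz) - radius) / wz) - 1);
      int k1 = std::min(nz - 1, (int)std::ceil((std::max(pz, qz) + radius) / wz) + 1);
      double r2 = radius * radius;
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            // quick reject on voxel centre
            double cx = (i + 0.5) * wx, cy = (j + 0.5) * wy, cz = (k + 0.5) * wz;
            double half = 0.5 * std::sqrt(wx * wx + wy * wy + wz * wz);
            double d2 = pt_seg_d2(cx, cy, cz, px, py, pz, qx, qy, qz);
            if (d2 > (radius + half) * (radius + half)) continue;
            int cnt = 0;
            for (int a = 0; a < ss; ++a)
              for (int b = 0; b < ss; ++b)
                for (int c = 0; c < ss; ++c) {
                  double sx = (i + (a + 0.5) / ss) * wx;
                  double sy = (j + (b + 0.5) / ss) * wy;
                  double sz = (k + (c + 0.5) / ss) * wz;
                  if (pt_seg_d2(sx, sy, sz, px, py, pz, qx, qy, qz) <= r2) ++cnt;
                }
            if (cnt > 0) {
              R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
              double val = cnt * inv;
              if (val > img[idx]) img[idx] = val;
            }
          }
    }
  }
  return img;
}

// centers (m x 3, um), semiaxes (m x 3, a >= b >= c), rot: list of 3x3
// rotation matrices whose COLUMNS are the ellipsoid principal axes in lab frame.
// [[Rcpp::export]]
NumericVector cpp_raster_ellipsoids(NumericMatrix centers, NumericMatrix semiaxes,
                                    List rot, IntegerVector dims,
                                    NumericVector spacing, NumericVector img) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double wx = spacing[0], wy = spacing[1], wz = spacing[2];
  const int ss = 3;
  const double inv = 1.0 / (ss * ss * ss);

  for (int m = 0; m < centers.nrow(); ++m) {
    NumericMatrix R = rot[m];
    double a = semiaxes(m, 0), b = semiaxes(m, 1), c = semiaxes(m, 2);
    double rmax = std::max(a, std::max(b, c));
    double cx = centers(m, 0), cy = centers(m, 1), cz = centers(m, 2);
    int i0 = std::max(0, (int)std::floor((cx - rmax) / wx) - 1);
    int i1 = std::min(nx - 1, (int)std::ceil((cx + rmax) / wx) + 1);
    int j0 = std::max(0, (int)std::floor((cy - rmax) / wy) - 1);
    int j1 = std::min(ny - 1, (int)std::ceil((cy + rmax) / wy) + 1);
    int k0 = std::max(0, (int)std::floor((cz - rmax) / wz) - 1);
    int k1 = std::min(nz - 1, (int)std::ceil((cz + rmax) / wz) + 1);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          int cnt = 0;
          for (int aa = 0; aa < ss; ++aa)
            for (int bb = 0; bb < ss; ++bb)
              for (int cc = 0; cc < ss; ++cc) {
                double sx = (i + (aa + 0.5) / ss) * wx - cx;
                double sy = (j + (bb + 0.5) / ss) * wy - cy;
                double sz = (k + (cc + 0.5) / ss) * wz - cz;
                // body frame: d = R^T s
                double dx = R(0, 0) * sx + R(1, 0) * sy + R(2, 0) * sz;
                double dy = R(0, 1) * sx + R(1, 1) * sy + R(2, 1) * sz;
                double dz = R(0, 2) * sx + R(1, 2) * sy + R(2, 2) * sz;
                double q = (dx / a) * (dx / a) + (dy / b) * (dy / b) + (dz / c) * (dz / c);
                if (q <= 1.0) ++cnt;
              }
          if (cnt > 0) {
            R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            double val = cnt * inv;
            if (val > img[idx]) img[idx] = val;
          }
        }
  }
  return img;
}

// Exact clipping of segments to a cubic grid of cell edge h starting at the
// origin. P, Q are (n x 3) segment endpoints in um; returns the summed length
// per cell (ncell = prod(nc)). Length outside the grid is dropped.
// [[Rcpp::export]]
NumericVector cpp_clip_segments(NumericMatrix P, NumericMatrix Q, double h,
                                IntegerVector nc) {
  const int cx = nc[0], cy = nc[1], cz = nc[2];
  NumericVector out((R_xlen_t)cx * cy * cz);
  std::vector<double> ts;
  for (int s = 0; s < P.nrow(); ++s) {
    double p[3] = {P(s, 0), P(s, 1), P(s, 2)};
    double q[3] = {Q(s, 0), Q(s, 1), Q(s, 2)};
    double len = std::sqrt((q[0] - p[0]) * (q[0] - p[0]) +
                           (q[1] - p[1]) * (q[1] - p[1]) +
                           (q[2] - p[2]) * (q[2] - p[2]));
    if (len == 0) continue;
    ts.clear();
    ts.push_back(0.0);
    ts.push_back(1.0);
    for (int a = 0; a < 3; ++a) {
      double lo = std::min(p[a], q[a]), hi = std::max(p[a], q[a]);
      if (q[a] == p[a]) continue;
      for (int m = (int)std::ceil(lo / h); m * h < hi; ++m) {
        if (m * h <= lo) continue;
        ts.push_back((m * h - p[a]) / (q[a] - p[a]));
      }
    }
    std::sort(ts.begin(), ts.end());
    for (size_t u = 0; u + 1 < ts.size(); ++u) {
      double t0 = ts[u], t1 = ts[u + 1];
      if (t1 <= t0) continue;
      double tm = 0.5 * (t0 + t1);
      int ii = (int)std::floor((p[0] + tm * (q[0] - p[0])) / h);
      int jj = (int)std::floor((p[1] + tm * (q[1] - p[1])) / h);
      int kk = (int)std::floor((p[2] + tm * (q[2] - p[2])) / h);
      if (ii < 0 || ii >= cx || jj < 0 || jj >= cy || kk < 0 || kk >= cz) continue;
      out[ii + (R_xlen_t)cx * (jj + (R_xlen_t)cy * kk)] += len * (t1 - t0);
    }
  }
  return out;
}
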