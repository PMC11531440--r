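// Low-level 3D image primitives shared by the phantom generator and the
// extraction pipeline. All arrays are R column-major: linear = i + nx*(j + ny*k).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline int reflect_index(int i, int n) {
  // reflect-101 boundary: ... 2 1 | 0 1 2 ... n-1 | n-2 n-3 ...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// Separable Gaussian blur; sigma given per axis in voxels (<= 0 skips the axis).
// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector img, IntegerVector dims,
                               NumericVector sigma_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> src(img.begin(), img.end());
  std::vector<double> dst(n);

  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int rad = (int)std::ceil(4.0 * s);
    std::vector<double> ker(2 * rad + 1);
    double tot = 0;
    for (int t = -rad; t <= rad; ++t) {
      ker[t + rad] = std::exp(-0.5 * (double)t * t / (s * s));
      tot += ker[t + rad];
    }
    for (auto &v : ker) v /= tot;

    int na;                 // length of a line along `axis`
    R_xlen_t stride;        // stride along `axis`
    int nl1, nl2;           // extents of the two orthogonal axes
    R_xlen_t st1, st2;      // their strides
    if (axis == 0) {
      na = nx; stride = 1;
      nl1 = ny; st1 = nx; nl2 = nz; st2 = (R_xlen_t)nx * ny;
    } else if (axis == 1) {
      na = ny; stride = nx;
      nl1 = nx; st1 = 1; nl2 = nz; st2 = (R_xlen_t)nx * ny;
    } else {
      na = nz; stride = (R_xlen_t)nx * ny;
      nl1 = nx; st1 = 1; nl2 = ny; st2 = nx;
    }
    for (int b = 0; b < nl2; ++b) {
      for (int a = 0; a < nl1; ++a) {
        R_xlen_t base = st1 * a + st2 * b;
        for (int p = 0; p < na; ++p) {
          double acc = 0;
          for (int t = -rad; t <= rad; ++t) {
            int q = reflect_index(p + t, na);
            acc += ker[t + rad] * src[base + stride * q];
          }
          dst[base + stride * p] = acc;
        }
      }
    }
    std::swap(src, dst);
  }
  NumericVector out(n);
  std::copy(src.begin(), src.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// 1D lower-envelope squared distance transform (Felzenszwalb & Huttenlocher)
// with physical sample spacing w.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 double w, std::vector<int> &v, std::vector<double> &z) {
  const double INF = std::numeric_limits<double>::infinity();
  // lower envelope over finite parabolas only
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double xq = q * w;
    double s;
    while (true) {
      double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) --k; else break; // z[0] = -INF guarantees termination
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (k < 0) { // whole line unresolved in this pass
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[j + 1] < xq) ++j;
    double xv = v[j] * w;
    d[q] = (xq - xv) * (xq - xv) + f[v[j]];
  }
}

// Squared Euclidean distance (um^2) from each TRUE voxel to the nearest FALSE
// voxel, with anisotropic voxel spacing. FALSE voxels get 0.
// [[Rcpp::export]]
NumericVector cpp_sq_edt(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = d[base + i];
      dt1d(f, g, nx, spacing[0], v, z);
      for (int i = 0; i < nx; ++i) d[base + i] = g[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = d[base + (R_xlen_t)nx * j];
      dt1d(f, g, ny, spacing[1], v, z);
      for (int j = 0; j < ny; ++j) d[base + (R_xlen_t)nx * j] = g[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = d[base + (R_xlen_t)nx * ny * k];
      dt1d(f, g, nz, spacing[2], v, z);
      for (int k = 0; k < nz; ++k) d[base + (R_xlen_t)nx * ny * k] = g[k];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (d[i] == INF) ? NA_REAL : d[i];
  out.attr("dim") = dims;
  return out;
}

// Connected-component labelling (6 or 26 connectivity), BFS, deterministic
// (components numbered by first-encountered linear index).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;

  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && man != 1) continue;
        offs.push_back(dx); offs.push_back(dy); offs.push_back(dz);
      }
  int noff = (int)offs.size() / 3;

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int ci = cur % nx;
      int cj = (cur / nx) % ny;
      int ck = cur / ((R_xlen_t)nx * ny);
      for (int t = 0; t < noff; ++t) {
        int xi = ci + offs[3 * t], yj = cj + offs[3 * t + 1], zk = ck + offs[3 * t + 2];
        if (xi < 0 || xi >= nx || yj < 0 || yj >= ny || zk < 0 || zk >= nz) continue;
        R_xlen_t q = xi + (R_xlen_t)nx * (yj + (R_xlen_t)ny * zk);
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// Union of balls: stamp a ball of radius r (um, anisotropic in voxel units)
// around each given voxel centre. coords are 0-based voxel indices (m x 3).
// [[Rcpp::export]]
LogicalVector cpp_stamp_balls(IntegerMatrix coords, NumericVector radii,
                              IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  out.attr("dim") = dims;
  for (int m = 0; m < coords.nrow(); ++m) {
    double r = radii[m];
    if (!(r > 0)) continue;
    int ci = coords(m, 0), cj = coords(m, 1), ck = coords(m, 2);
    int ri = (int)std::floor(r / spacing[0]);
    int rj = (int)std::floor(r / spacing[1]);
    int rk = (int)std::floor(r / spacing[2]);
    double r2 = r * r;
    for (int k = std::max(0, ck - rk); k <= std::min(nz - 1, ck + rk); ++k)
      for (int j = std::max(0, cj - rj); j <= std::min(ny - 1, cj + rj); ++j)
        for (int i = std::max(0, ci - ri); i <= std::min(nx - 1, ci + ri); ++i) {
          double dx = (i - ci) * spacing[0];
          double dy = (j - cj) * spacing[1];
          double dz = (k - ck) * spacing[2];
          if (dx * dx + dy * dy + dz * dz <= r2)
            out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
        }
  }
  return out;
}

// Thin points retained by a sequential hard-core rule: a point is kept iff it
// is at least min_dist from every previously kept point. Deterministic in the
// given row order.
// [[Rcpp::export]]
LogicalVector cpp_hardcore_keep(NumericMatrix pts, double min_dist,
                                NumericVector domain) {
  int n = pts.nrow();
  LogicalVector keep(n, false);
  if (n == 0) return keep;
  double cell = std::max(min_dist, 1e-6);
  int gx = std::max(1, (int)std::ceil(domain[0] / cell));
  int gy = std::max(1, (int)std::ceil(domain[1] / cell));
  int gz = std::max(1, (int)std::ceil(domain[2] / cell));
  std::vector<std::vector<int>> bins((size_t)gx * gy * gz);
  double md2 = min_dist * min_dist;
  for (int m = 0; m < n; ++m) {
    int bi = std::min(gx - 1, std::max(0, (int)(pts(m, 0) / cell)));
    int bj = std::min(gy - 1, std::max(0, (int)(pts(m, 1) / cell)));
    int bk = std::min(gz - 1, std::max(0, (int)(pts(m, 2) / cell)));
    bool ok = true;
    for (int k = std::max(0, bk - 1); ok && k <= std::min(gz - 1, bk + 1); ++k)
      for (int j = std::max(0, bj - 1); ok && j <= std::min(gy - 1, bj + 1); ++j)
        for (int i = std::max(0, bi - 1); ok && i <= std::min(gx - 1, bi + 1); ++i)
          for (int q : bins[i + (size_t)gx * (j + (size_t)gy * k)]) {
            double dx = pts(m, 0) - pts(q, 0), dy = pts(m, 1) - pts(q, 1),
                   dz = pts(m, 2) - pts(q, 2);
            if (dx * dx + dy * dy + dz * dz < md2) { ok = false; break; }
          }
    if (ok) {
      keep[m] = true;
      bins[bi + (size_t)gx * (bj + (size_t)gy * bk)].push_back(m);
    }
  }
  return keep;
}
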