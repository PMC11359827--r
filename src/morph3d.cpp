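#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// All masks are logical 3D arrays passed as LogicalVector plus an explicit
// dim vector; voxel indices inside this file are 0-based linear, column-major
// (R layout). Offsets come in as an n x 3 integer matrix of (dx, dy, dz).

static inline bool in_bounds(int x, int y, int z, const int *d) {
  return x >= 0 && x < d[0] && y >= 0 && y < d[1] && z >= 0 && z < d[2];
}

// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dim,
                         IntegerMatrix offsets) {
  int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t n = mask.size();
  LogicalVector out(n);
  int noff = offsets.nrow();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int x = (int)(i % d[0]);
    int y = (int)((i / d[0]) % d[1]);
    int z = (int)(i / ((R_xlen_t)d[0] * d[1]));
    for (int k = 0; k < noff; ++k) {
      int xx = x + offsets(k, 0), yy = y + offsets(k, 1), zz = z + offsets(k, 2);
      if (in_bounds(xx, yy, zz, d))
        out[(R_xlen_t)xx + (R_xlen_t)d[0] * (yy + (R_xlen_t)d[1] * zz)] = true;
    }
  }
  return out;
}

// Erosion with out-of-bounds treated as background (standard zero padding).
// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dim,
                        IntegerMatrix offsets) {
  int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t n = mask.size();
  LogicalVector out(n);
  int noff = offsets.nrow();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int x = (int)(i % d[0]);
    int y = (int)((i / d[0]) % d[1]);
    int z = (int)(i / ((R_xlen_t)d[0] * d[1]));
    bool keep = true;
    for (int k = 0; k < noff && keep; ++k) {
      int xx = x + offsets(k, 0), yy = y + offsets(k, 1), zz = z + offsets(k, 2);
      if (!in_bounds(xx, yy, zz, d) ||
          !mask[(R_xlen_t)xx + (R_xlen_t)d[0] * (yy + (R_xlen_t)d[1] * zz)])
        keep = false;
    }
    out[i] = keep;
  }
  return out;
}

static void neighbour_offsets(int connectivity, std::vector<int> &dx,
                              std::vector<int> &dy, std::vector<int> &dz) {
  if (connectivity == 6) {
    int fx[6] = {1, -1, 0, 0, 0, 0};
    int fy[6] = {0, 0, 1, -1, 0, 0};
    int fz[6] = {0, 0, 0, 0, 1, -1};
    dx.assign(fx, fx + 6); dy.assign(fy, fy + 6); dz.assign(fz, fz + 6);
  } else {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          dx.push_back(a); dy.push_back(b); dz.push_back(c);
        }
  }
}

// Label connected components; labels assigned 1..n in column-major scan order
// of each component's first voxel (deterministic).
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dim,
                        int connectivity) {
  int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++cur;
    stack.clear();
    stack.push_back(i);
    lab[i] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = (int)(v % d[0]);
      int y = (int)((v / d[0]) % d[1]);
      int z = (int)(v / ((R_xlen_t)d[0] * d[1]));
      for (size_t k = 0; k < dx.size(); ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (!in_bounds(xx, yy, zz, d)) continue;
        R_xlen_t u = (R_xlen_t)xx + (R_xlen_t)d[0] * (yy + (R_xlen_t)d[1] * zz);
        if (mask[u] && !lab[u]) { lab[u] = cur; stack.push_back(u); }
      }
    }
  }
  return lab;
}

// Background (mask == FALSE) voxels 6-connected to the array border.
// [[Rcpp::export]]
LogicalVector cpp_border_background(LogicalVector mask, IntegerVector dim) {
  int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t n = mask.size();
  LogicalVector vis(n);
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    int x = (int)(i % d[0]);
    int y = (int)((i / d[0]) % d[1]);
    int z = (int)(i / ((R_xlen_t)d[0] * d[1]));
    bool border = (x == 0 || x == d[0] - 1 || y == 0 || y == d[1] - 1 ||
                   z == 0 || z == d[2] - 1);
    if (border && !mask[i] && !vis[i]) { vis[i] = true; stack.push_back(i); }
  }
  int fx[6] = {1, -1, 0, 0, 0, 0};
  int fy[6] = {0, 0, 1, -1, 0, 0};
  int fz[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    R_xlen_t v = stack.back(); stack.pop_back();
    int x = (int)(v % d[0]);
    int y = (int)((v / d[0]) % d[1]);
    int z = (int)(v / ((R_xlen_t)d[0] * d[1]));
    for (int k = 0; k < 6; ++k) {
      int xx = x + fx[k], yy = y + fy[k], zz = z + fz[k];
      if (!in_bounds(xx, yy, zz, d)) continue;
      R_xlen_t u = (R_xlen_t)xx + (R_xlen_t)d[0] * (yy + (R_xlen_t)d[1] * zz);
      if (!mask[u] && !vis[u]) { vis[u] = true; stack.push_back(u); }
    }
  }
  return vis;
}

// One full wavefront attempt at a fixed threshold (Eqs. 7-9 loop).
// Front-queue formulation, equivalent to repeated Sphere(1) dilation with
// threshold judgment: a candidate is accepted iff it is inside `region`, not
// in `forbidden`, and hu - seed_hu < threshold.
// leak codes: 0 none, 1 iteration cap exceeded, 2 growth rule fired.
// cap_iters < 0 or growth_cap < 0 disable the respective rule.
// [[Rcpp::export]]
List cpp_segment_attempt(IntegerVector hu, LogicalVector region,
                         LogicalVector forbidden, IntegerVector seeds,
                         IntegerVector dim, int seed_hu, int threshold,
                         int cap_iters, double growth_cap) {
  int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t n = hu.size();
  LogicalVector X(n);
  std::vector<R_xlen_t> front, nextf;
  for (R_xlen_t k = 0; k < seeds.size(); ++k) {
    R_xlen_t i = (R_xlen_t)seeds[k] - 1; // 1-based from R
    if (!X[i]) { X[i] = true; front.push_back(i); }
  }
  int fx[6] = {1, -1, 0, 0, 0, 0};
  int fy[6] = {0, 0, 1, -1, 0, 0};
  int fz[6] = {0, 0, 0, 0, 1, -1};
  int iter = 0, leak = 0;
  while (!front.empty()) {
    nextf.clear();
    for (size_t q = 0; q < front.size(); ++q) {
      R_xlen_t v = front[q];
      int x = (int)(v % d[0]);
      int y = (int)((v / d[0]) % d[1]);
      int z = (int)(v / ((R_xlen_t)d[0] * d[1]));
      for (int k = 0; k < 6; ++k) {
        int xx = x + fx[k], yy = y + fy[k], zz = z + fz[k];
        if (!in_bounds(xx, yy, zz, d)) continue;
        R_xlen_t u = (R_xlen_t)xx + (R_xlen_t)d[0] * (yy + (R_xlen_t)d[1] * zz);
        if (X[u] || !region[u] || forbidden[u]) continue;
        if (hu[u] - seed_hu >= threshold) continue; // Eq. 8 rejection
        X[u] = true;
        nextf.push_back(u);
      }
    }
    if (nextf.empty()) break;
    bool over_iters = (cap_iters >= 0 && iter + 1 > cap_iters);
    bool over_growth = (growth_cap >= 0 && (double)nextf.size() > growth_cap);
    if (over_iters || over_growth) {
      // X is returned as-is (including the offending layer): on a leak the
      // caller resets to the seed set but keeps this state as the leaky
      // segmentation used for gap localization
      leak = over_growth ? 2 : 1;
      break;
    }
    ++iter;
    front.swap(nextf);
  }
  return List::create(_["X"] = X, _["iterations"] = iter, _["leak"] = leak);
}
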