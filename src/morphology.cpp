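#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Voxel-level primitives for lung extraction. All arrays are column-major
// logical/int vectors with an explicit (nx, ny, nz) dim, matching R arrays.

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// 6-connected component labelling by breadth-first search.
// Returns integer labels, 0 = background, components numbered from 1 in
// decreasing voxel-count order (label 1 is the largest component).
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  std::vector<int> queue;
  queue.reserve(1024);
  int next = 0;
  std::vector<R_xlen_t> sizes;

  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};

  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int i = lin(x, y, z, nx, ny);
        if (!mask[i] || lab[i] != 0) continue;
        ++next;
        R_xlen_t count = 0;
        lab[i] = next;
        queue.clear();
        queue.push_back(i);
        while (!queue.empty()) {
          int cur = queue.back();
          queue.pop_back();
          ++count;
          int cz = cur / (nx * ny);
          int rem = cur - cz * nx * ny;
          int cy = rem / nx;
          int cx = rem - cy * nx;
          for (int k = 0; k < 6; ++k) {
            int ax = cx + dx[k], ay = cy + dy[k], az = cz + dz[k];
            if (ax < 0 || ax >= nx || ay < 0 || ay >= ny || az < 0 || az >= nz)
              continue;
            int j = lin(ax, ay, az, nx, ny);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              queue.push_back(j);
            }
          }
        }
        sizes.push_back(count);
      }
    }
  }

  // relabel so that label 1 is the largest component
  if (next > 1) {
    std::vector<int> order(next);
    for (int k = 0; k < next; ++k) order[k] = k;
    std::stable_sort(order.begin(), order.end(),
                     [&](int a, int b) { return sizes[a] > sizes[b]; });
    std::vector<int> remap(next + 1, 0);
    for (int k = 0; k < next; ++k) remap[order[k] + 1] = k + 1;
    for (R_xlen_t i = 0; i < n; ++i)
      if (lab[i]) lab[i] = remap[lab[i]];
  }
  lab.attr("n_components") = next;
  return lab;
}

// [[Rcpp::export(name = ".binary_dilate_3d")]]
LogicalVector binary_dilate_3d(LogicalVector mask, IntegerVector dim,
                               IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = mask.size();
  LogicalVector out(n, false);
  const int m = offsets.nrow();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = lin(x, y, z, nx, ny);
        if (!mask[i]) continue;
        for (int k = 0; k < m; ++k) {
          int ax = x + offsets(k, 0), ay = y + offsets(k, 1),
              az = z + offsets(k, 2);
          if (ax < 0 || ax >= nx || ay < 0 || ay >= ny || az < 0 || az >= nz)
            continue;
          out[lin(ax, ay, az, nx, ny)] = true;
        }
      }
  return out;
}

// Erosion with the voxel outside the volume treated as background.
// [[Rcpp::export(name = ".binary_erode_3d")]]
LogicalVector binary_erode_3d(LogicalVector mask, IntegerVector dim,
                              IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = mask.size();
  LogicalVector out(n, false);
  const int m = offsets.nrow();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = lin(x, y, z, nx, ny);
        if (!mask[i]) continue;
        bool keep = true;
        for (int k = 0; k < m && keep; ++k) {
          int ax = x + offsets(k, 0), ay = y + offsets(k, 1),
              az = z + offsets(k, 2);
          if (ax < 0 || ax >= nx || ay < 0 || ay >= ny || az < 0 || az >= nz ||
              !mask[lin(ax, ay, az, nx, ny)])
            keep = false;
        }
        out[i] = keep;
      }
  return out;
}

// Per-axial-slice hole filling: background 4-connected to the slice border
// stays background; enclosed background is filled. Fills vessel and lesion
// voxels excluded by the air threshold back into the lung interior.
// [[Rcpp::export(name = ".fill_holes_slicewise")]]
LogicalVector fill_holes_slicewise(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out = clone(mask);
  std::vector<char> reach(static_cast<size_t>(nx) * ny);
  std::vector<int> queue;
  const int dx[4] = {-1, 1, 0, 0};
  const int dy[4] = {0, 0, -1, 1};

  for (int z = 0; z < nz; ++z) {
    std::fill(reach.begin(), reach.end(), 0);
    queue.clear();
    const int base = nx * ny * z;
    // seed from slice border background
    for (int x = 0; x < nx; ++x) {
      for (int y : {0, ny - 1}) {
        int s = x + nx * y;
        if (!mask[base + s] && !reach[s]) { reach[s] = 1; queue.push_back(s); }
      }
    }
    for (int y = 0; y < ny; ++y) {
      for (int x : {0, nx - 1}) {
        int s = x + nx * y;
        if (!mask[base + s] && !reach[s]) { reach[s] = 1; queue.push_back(s); }
      }
    }
    while (!queue.empty()) {
      int cur = queue.back();
      queue.pop_back();
      int cy = cur / nx, cx = cur - cy * nx;
      for (int k = 0; k < 4; ++k) {
        int ax = cx + dx[k], ay = cy + dy[k];
        if (ax < 0 || ax >= nx || ay < 0 || ay >= ny) continue;
        int s = ax + nx * ay;
        if (!mask[base + s] && !reach[s]) { reach[s] = 1; queue.push_back(s); }
      }
    }
    for (int s = 0; s < nx * ny; ++s)
      if (!mask[base + s] && !reach[s]) out[base + s] = true;
  }
  return out;
}

// Exact two-sided permutation p-value for Spearman's rank correlation.
// rx, ry are (mid)ranks; enumerates all distinct permutations of ry
// (std::next_permutation over the multiset handles ties correctly).
// Feasible for n <= 10.
// [[Rcpp::export(name = ".spearman_perm_pvalue")]]
double spearman_perm_pvalue(NumericVector rx, NumericVector ry) {
  const int n = rx.size();
  std::vector<double> a(rx.begin(), rx.end());
  std::vector<double> b(ry.begin(), ry.end());
  double sa = 0, sb = 0;
  for (int i = 0; i < n; ++i) { sa += a[i]; sb += b[i]; }
  const double ma = sa / n, mb = sb / n;
  double obs = 0;
  for (int i = 0; i < n; ++i) obs += (a[i] - ma) * (b[i] - mb);
  const double obs_abs = std::fabs(obs) - 1e-9;

  std::sort(b.begin(), b.end());
  double total = 0, extreme = 0;
  do {
    double s = 0;
    for (int i = 0; i < n; ++i) s += (a[i] - ma) * (b[i] - mb);
    total += 1;
    if (std::fabs(s) >= obs_abs) extreme += 1;
  } while (std::next_permutation(b.begin(), b.end()));
  return extreme / total;
}
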