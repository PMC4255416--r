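#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 3D binary morphology and connected-component machinery shared by the
// brain-extraction, CSF-splitting and lesion-classification stages.
// Arrays are passed as flat logical/integer vectors in R's column-major
// layout with explicit dims; indices are 0-based internally.

static void neighbor_offsets(int connectivity, std::vector<int>& dx,
                             std::vector<int>& dy, std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, dx, dy, dz);
  int ncomp = 0;
  std::vector<int> stack;
  for (int z0 = 0; z0 < nz; ++z0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int x0 = 0; x0 < nx; ++x0) {
        int i0 = idx3(x0, y0, z0, nx, ny);
        if (!mask[i0] || lab[i0]) continue;
        ++ncomp;
        stack.clear();
        stack.push_back(i0);
        lab[i0] = ncomp;
        while (!stack.empty()) {
          int i = stack.back(); stack.pop_back();
          int z = i / (nx * ny), r = i % (nx * ny);
          int y = r / nx, x = r % nx;
          for (size_t k = 0; k < dx.size(); ++k) {
            int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int j = idx3(xx, yy, zz, nx, ny);
            if (mask[j] && !lab[j]) { lab[j] = ncomp; stack.push_back(j); }
          }
        }
      }
  return lab;
}

// One dilation step per unit of Chebyshev (26-connectivity) or city-block
// (6-connectivity) radius. Outside the volume counts as background.
// [[Rcpp::export(name = ".dilate")]]
LogicalVector dilate_mask(LogicalVector mask, IntegerVector dims, int radius,
                          int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, dx, dy, dz);
  LogicalVector cur = clone(mask);
  for (int r = 0; r < radius; ++r) {
    LogicalVector nxt = clone(cur);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = idx3(x, y, z, nx, ny);
          if (cur[i]) continue;
          for (size_t k = 0; k < dx.size(); ++k) {
            int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            if (cur[idx3(xx, yy, zz, nx, ny)]) { nxt[i] = true; break; }
          }
        }
    cur = nxt;
  }
  return cur;
}

// Erosion; voxels outside the volume count as foreground so the mask is not
// eaten at the array border.
// [[Rcpp::export(name = ".erode")]]
LogicalVector erode_mask(LogicalVector mask, IntegerVector dims, int radius,
                         int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, dx, dy, dz);
  LogicalVector cur = clone(mask);
  for (int r = 0; r < radius; ++r) {
    LogicalVector nxt = clone(cur);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = idx3(x, y, z, nx, ny);
          if (!cur[i]) continue;
          for (size_t k = 0; k < dx.size(); ++k) {
            int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            if (!cur[idx3(xx, yy, zz, nx, ny)]) { nxt[i] = false; break; }
          }
        }
    cur = nxt;
  }
  return cur;
}

// Fill fully enclosed background cavities: flood the complement from the
// array faces (6-connectivity); anything unreached is a hole.
// [[Rcpp::export(name = ".fill_holes")]]
LogicalVector fill_holes(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = mask.size();
  std::vector<char> outside(n, 0);
  std::vector<int> dx, dy, dz;
  neighbor_offsets(6, dx, dy, dz);
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x != 0 && y != 0 && z != 0 && x != nx - 1 && y != ny - 1 && z != nz - 1)
          continue;
        int i = idx3(x, y, z, nx, ny);
        if (!mask[i] && !outside[i]) { outside[i] = 1; stack.push_back(i); }
      }
  while (!stack.empty()) {
    int i = stack.back(); stack.pop_back();
    int z = i / (nx * ny), r = i % (nx * ny);
    int y = r / nx, x = r % nx;
    for (size_t k = 0; k < dx.size(); ++k) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      int j = idx3(xx, yy, zz, nx, ny);
      if (!mask[j] && !outside[j]) { outside[j] = 1; stack.push_back(j); }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  return out;
}

// Count, for every voxel, how many of its 26 neighbors have `flag` set.
// [[Rcpp::export(name = ".neighbor_count")]]
IntegerVector neighbor_count(LogicalVector flag, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> dx, dy, dz;
  neighbor_offsets(26, dx, dy, dz);
  IntegerVector out(flag.size(), 0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        int cnt = 0;
        for (size_t k = 0; k < dx.size(); ++k) {
          int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          if (flag[idx3(xx, yy, zz, nx, ny)]) ++cnt;
        }
        out[i] = cnt;
      }
  return out;
}
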