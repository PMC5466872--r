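#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel lattices arrive as R arrays in column-major order with dims
// (nx, ny, nz); linear index = x + nx*(y + ny*z), all 0-based here.

static inline bool in_bounds(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// [[Rcpp::export(name = ".erode_cpp")]]
LogicalVector erode_cpp(LogicalVector mask, IntegerVector dim,
                        IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int no = offsets.nrow();
  LogicalVector out(mask.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t idx = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (!mask[idx]) { out[idx] = false; continue; }
        bool keep = true;
        for (int o = 0; o < no; ++o) {
          const int xx = x + offsets(o, 0);
          const int yy = y + offsets(o, 1);
          const int zz = z + offsets(o, 2);
          // outside the lattice counts as background
          if (!in_bounds(xx, yy, zz, nx, ny, nz) ||
              !mask[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)]) {
            keep = false; break;
          }
        }
        out[idx] = keep;
      }
  return out;
}

// [[Rcpp::export(name = ".dilate_cpp")]]
LogicalVector dilate_cpp(LogicalVector mask, IntegerVector dim,
                         IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int no = offsets.nrow();
  LogicalVector out(mask.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t idx = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        bool hit = false;
        for (int o = 0; o < no; ++o) {
          const int xx = x + offsets(o, 0);
          const int yy = y + offsets(o, 1);
          const int zz = z + offsets(o, 2);
          if (in_bounds(xx, yy, zz, nx, ny, nz) &&
              mask[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)]) {
            hit = true; break;
          }
        }
        out[idx] = hit;
      }
  return out;
}

// 26-connected component labelling over voxels where levels > 0.
// Returns integer labels (0 = background), components numbered from 1.
// When by_level is true, neighbours must share the same level value
// (equal-level zones, as used by the size-zone matrix).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(IntegerVector levels, IntegerVector dim,
                                   bool by_level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = levels.size();
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (levels[start] <= 0 || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    stack.clear();
    stack.push_back(start);
    const int lev = levels[start];
    while (!stack.empty()) {
      const R_xlen_t idx = stack.back(); stack.pop_back();
      const int x = (int)(idx % nx);
      const int y = (int)((idx / nx) % ny);
      const int z = (int)(idx / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int xx = x + dx, yy = y + dy, zz = z + dz;
            if (!in_bounds(xx, yy, zz, nx, ny, nz)) continue;
            const R_xlen_t nidx = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (labels[nidx] != 0 || levels[nidx] <= 0) continue;
            if (by_level && levels[nidx] != lev) continue;
            labels[nidx] = next_label;
            stack.push_back(nidx);
          }
    }
  }
  return labels;
}

// Symmetric gray-level co-occurrence counts for one voxel offset.
// levels: 0 outside the mask, 1..n_levels inside. Counts each ordered
// in-mask pair once; symmetrisation is done in R.
// [[Rcpp::export(name = ".glcm_counts_cpp")]]
NumericMatrix glcm_counts_cpp(IntegerVector levels, IntegerVector dim,
                              int n_levels, IntegerVector offset) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int dx = offset[0], dy = offset[1], dz = offset[2];
  NumericMatrix counts(n_levels, n_levels);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int a = levels[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
        if (a <= 0) continue;
        const int xx = x + dx, yy = y + dy, zz = z + dz;
        if (!in_bounds(xx, yy, zz, nx, ny, nz)) continue;
        const int b = levels[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
        if (b <= 0) continue;
        counts(a - 1, b - 1) += 1.0;
      }
  return counts;
}

// Run-length counts for one direction: maximal collinear segments of
// equal level lying entirely inside the mask. Matrix is
// n_levels x max_run_len (padded to the longest lattice axis).
// [[Rcpp::export(name = ".glrlm_counts_cpp")]]
NumericMatrix glrlm_counts_cpp(IntegerVector levels, IntegerVector dim,
                               int n_levels, IntegerVector direction) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int dx = direction[0], dy = direction[1], dz = direction[2];
  int max_len = nx;
  if (ny > max_len) max_len = ny;
  if (nz > max_len) max_len = nz;
  NumericMatrix counts(n_levels, max_len);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int a = levels[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
        if (a <= 0) continue;
        // run starts where the previous voxel along -direction is not a
        // same-level in-mask voxel
        const int px = x - dx, py = y - dy, pz = z - dz;
        if (in_bounds(px, py, pz, nx, ny, nz) &&
            levels[px + (R_xlen_t)nx * (py + (R_xlen_t)ny * pz)] == a)
          continue;
        int len = 1;
        int xx = x + dx, yy = y + dy, zz = z + dz;
        while (in_bounds(xx, yy, zz, nx, ny, nz) &&
               levels[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] == a) {
          ++len; xx += dx; yy += dy; zz += dz;
        }
        counts(a - 1, len - 1) += 1.0;
      }
  return counts;
}

// Gray-level dependence: for every in-mask voxel, 1 (itself) plus the
// number of 26-neighbours inside the mask whose level differs by at
// most alpha. Returns a 2-column matrix (level, dependence).
// [[Rcpp::export(name = ".gldm_counts_cpp")]]
IntegerMatrix gldm_counts_cpp(IntegerVector levels, IntegerVector dim,
                              int alpha) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> lev_out, dep_out;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int a = levels[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
        if (a <= 0) continue;
        int dep = 1;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int xx = x + dx, yy = y + dy, zz = z + dz;
              if (!in_bounds(xx, yy, zz, nx, ny, nz)) continue;
              const int b =
                levels[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
              if (b > 0 && std::abs(b - a) <= alpha) ++dep;
            }
        lev_out.push_back(a);
        dep_out.push_back(dep);
      }
  IntegerMatrix out(lev_out.size(), 2);
  for (size_t i = 0; i < lev_out.size(); ++i) {
    out(i, 0) = lev_out[i];
    out(i, 1) = dep_out[i];
  }
  return out;
}

// Neighbourhood gray-tone difference accumulators: for each level i,
// n_i (count of contributing voxels) and s_i (summed absolute
// difference from the mean of in-mask 26-neighbours). Voxels with no
// in-mask neighbour do not contribute.
// [[Rcpp::export(name = ".ngtdm_counts_cpp")]]
NumericMatrix ngtdm_counts_cpp(IntegerVector levels, IntegerVector dim,
                               int n_levels) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(n_levels, 2);  // columns: n_i, s_i
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int a = levels[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
        if (a <= 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int xx = x + dx, yy = y + dy, zz = z + dz;
              if (!in_bounds(xx, yy, zz, nx, ny, nz)) continue;
              const int b =
                levels[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
              if (b > 0) { sum += b; ++cnt; }
            }
        if (cnt == 0) continue;
        out(a - 1, 0) += 1.0;
        out(a - 1, 1) += std::fabs((double)a - sum / cnt);
      }
  return out;
}

// Exact 2-D Euclidean distance transform (Felzenszwalb & Huttenlocher)
// of a binary slice: distance in mm from each foreground pixel to the
// nearest background pixel, with pixel sizes (sx, sy). Background
// pixels get 0; the lattice edge also counts as background.
static void dt_1d(const std::vector<double> &f, std::vector<double> &d,
                  double step) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> zpts(n + 1);
  int k = 0;
  v[0] = 0;
  zpts[0] = -INFINITY;
  zpts[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const double qq = (double)q * step, vv = (double)v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * (qq - vv));
      if (s > zpts[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    zpts[k] = s;
    zpts[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double qq = (double)q * step;
    while (zpts[k + 1] < qq) ++k;
    const double vv = (double)v[k] * step;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt2d_cpp")]]
NumericMatrix edt2d_cpp(LogicalMatrix slice, double sx, double sy) {
  const int nx = slice.nrow(), ny = slice.ncol();
  // pad by one background pixel on every side so the edge is background
  const int px = nx + 2, py = ny + 2;
  std::vector<double> g(px * py);
  const double big = 1e20;
  for (int y = 0; y < py; ++y)
    for (int x = 0; x < px; ++x) {
      bool fg = (x >= 1 && x <= nx && y >= 1 && y <= ny) &&
                slice(x - 1, y - 1);
      g[x + px * y] = fg ? big : 0.0;
    }
  std::vector<double> col(py), dcol(py);
  for (int x = 0; x < px; ++x) {
    for (int y = 0; y < py; ++y) col[y] = g[x + px * y];
    dt_1d(col, dcol, sy);
    for (int y = 0; y < py; ++y) g[x + px * y] = dcol[y];
  }
  std::vector<double> row(px), drow(px);
  NumericMatrix out(nx, ny);
  for (int y = 0; y < py; ++y) {
    for (int x = 0; x < px; ++x) row[x] = g[x + px * y];
    dt_1d(row, drow, sx);
    if (y >= 1 && y <= ny)
      for (int x = 1; x <= nx; ++x)
        out(x - 1, y - 1) = std::sqrt(drow[x]);
  }
  return out;
}
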