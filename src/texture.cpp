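#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Voxel grids arrive as flat integer vectors in R's column-major order:
// idx = x + nx*(y + ny*z), 0-based. Level 0 marks voxels outside the VOI;
// in-VOI voxels carry discretized levels 1..ng.

static inline int vox(const IntegerVector &lv, int nx, int ny, int nz,
                      int x, int y, int z) {
  if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
  return lv[x + nx * (y + (R_xlen_t)ny * z)];
}

// Symmetric grey-level co-occurrence counts, one ng x ng slab per offset.
// Each ordered pair is counted in both orders (symmetric GLCM).
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector lv, int nx, int ny, int nz, int ng,
                       IntegerMatrix offsets) {
  int nd = offsets.nrow();
  NumericVector out((R_xlen_t)ng * ng * nd);
  out.attr("dim") = IntegerVector::create(ng, ng, nd);
  for (int d = 0; d < nd; ++d) {
    int ox = offsets(d, 0), oy = offsets(d, 1), oz = offsets(d, 2);
    double *slab = out.begin() + (R_xlen_t)d * ng * ng;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = vox(lv, nx, ny, nz, x, y, z);
          if (a == 0) continue;
          int b = vox(lv, nx, ny, nz, x + ox, y + oy, z + oz);
          if (b == 0) continue;
          slab[(a - 1) + ng * (b - 1)] += 1.0;
          slab[(b - 1) + ng * (a - 1)] += 1.0;
        }
  }
  return out;
}

// Run-length counts: maximal runs of a constant level along each offset.
// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector lv, int nx, int ny, int nz, int ng,
                        IntegerMatrix offsets, int maxlen) {
  int nd = offsets.nrow();
  NumericVector out((R_xlen_t)ng * maxlen * nd);
  out.attr("dim") = IntegerVector::create(ng, maxlen, nd);
  for (int d = 0; d < nd; ++d) {
    int ox = offsets(d, 0), oy = offsets(d, 1), oz = offsets(d, 2);
    double *slab = out.begin() + (R_xlen_t)d * ng * maxlen;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = vox(lv, nx, ny, nz, x, y, z);
          if (a == 0) continue;
          // only start a run where the previous voxel along -offset differs
          if (vox(lv, nx, ny, nz, x - ox, y - oy, z - oz) == a) continue;
          int len = 1;
          int cx = x + ox, cy = y + oy, cz = z + oz;
          while (vox(lv, nx, ny, nz, cx, cy, cz) == a) {
            ++len; cx += ox; cy += oy; cz += oz;
          }
          if (len > maxlen) len = maxlen;
          slab[(a - 1) + ng * (len - 1)] += 1.0;
        }
  }
  return out;
}

// Size-zone enumeration: 26-connected components of constant level.
// Returns an nzones x 2 matrix of (level, size).
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector lv, int nx, int ny, int nz) {
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> levels, sizes, stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seen[i] || lv[i] == 0) continue;
    int lev = lv[i], size = 0;
    stack.clear(); stack.push_back((int)i); seen[i] = 1;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back(); ++size;
      int cx = cur % nx, rem = cur / nx, cy = rem % ny, cz = rem / ny;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz)
              continue;
            R_xlen_t j = x + nx * (y + (R_xlen_t)ny * z);
            if (!seen[j] && lv[j] == lev) { seen[j] = 1; stack.push_back((int)j); }
          }
    }
    levels.push_back(lev); sizes.push_back(size);
  }
  IntegerMatrix out(levels.size(), 2);
  for (size_t k = 0; k < levels.size(); ++k) {
    out(k, 0) = levels[k]; out(k, 1) = sizes[k];
  }
  return out;
}

// Neighbourhood grey-tone difference: per level, the summed absolute
// difference between the centre level and the mean of its in-VOI
// 26-neighbours, plus the count of contributing voxels.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector lv, int nx, int ny, int nz, int ng) {
  NumericMatrix out(ng, 2); // columns: s_i, n_i
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = vox(lv, nx, ny, nz, x, y, z);
        if (a == 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int b = vox(lv, nx, ny, nz, x + dx, y + dy, z + dz);
              if (b > 0) { sum += b; ++cnt; }
            }
        if (cnt > 0) {
          out(a - 1, 0) += std::abs(a - sum / cnt);
          out(a - 1, 1) += 1.0;
        }
      }
  return out;
}

// Dependence counts: per voxel, the number of in-VOI 26-neighbours whose
// level differs from the centre by at most alpha. Column j holds dependence
// j-1 (0..26 neighbours).
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector lv, int nx, int ny, int nz, int ng,
                       int alpha) {
  NumericMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = vox(lv, nx, ny, nz, x, y, z);
        if (a == 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int b = vox(lv, nx, ny, nz, x + dx, y + dy, z + dz);
              if (b > 0 && std::abs(b - a) <= alpha) ++dep;
            }
        out(a - 1, dep) += 1.0;
      }
  return out;
}
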