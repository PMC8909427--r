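#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// The 13 unique 3D offsets at Chebyshev distance 1 (half of the 26-neighborhood);
// with symmetric accumulation they cover all 26 directions.
static const int NDIR = 13;
static const int DIRS[NDIR][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline bool in_grid(int i, int j, int k, int nx, int ny, int nz) {
  return i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz;
}

// levels: 3D integer grid, 0 outside the ROI, 1..ng inside.

//' Symmetric co-occurrence counts, distance 1, one ng x ng slab per direction.
//' @noRd
// [[Rcpp::export(name = ".cpp_glcm_counts")]]
NumericVector cpp_glcm_counts(IntegerVector levels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(Dimension(ng, ng, NDIR));
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int lv = levels[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        if (lv == 0) continue;
        for (int d = 0; d < NDIR; ++d) {
          int ii = i + DIRS[d][0], jj = j + DIRS[d][1], kk = k + DIRS[d][2];
          if (!in_grid(ii, jj, kk, nx, ny, nz)) continue;
          int lw = levels[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
          if (lw == 0) continue;
          out[(lv - 1) + ng * (lw - 1) + (R_xlen_t)ng * ng * d] += 1.0;
          out[(lw - 1) + ng * (lv - 1) + (R_xlen_t)ng * ng * d] += 1.0;
        }
      }
  return out;
}

//' Run-length counts: ng x max_run slab per direction.
//' @noRd
// [[Rcpp::export(name = ".cpp_glrlm_counts")]]
NumericVector cpp_glrlm_counts(IntegerVector levels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int maxrun = std::max(nx, std::max(ny, nz));
  NumericVector out(Dimension(ng, maxrun, NDIR));
  for (int d = 0; d < NDIR; ++d) {
    const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int lv = levels[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
          if (lv == 0) continue;
          // run start: predecessor along the direction is absent or differs
          int pi = i - dx, pj = j - dy, pk = k - dz;
          if (in_grid(pi, pj, pk, nx, ny, nz) &&
              levels[pi + (R_xlen_t)nx * (pj + (R_xlen_t)ny * pk)] == lv)
            continue;
          int len = 1;
          int ci = i + dx, cj = j + dy, ck = k + dz;
          while (in_grid(ci, cj, ck, nx, ny, nz) &&
                 levels[ci + (R_xlen_t)nx * (cj + (R_xlen_t)ny * ck)] == lv) {
            ++len;
            ci += dx; cj += dy; ck += dz;
          }
          out[(lv - 1) + ng * (len - 1) + (R_xlen_t)ng * maxrun * d] += 1.0;
        }
  }
  return out;
}

//' Dependence counts (alpha tolerance on |level difference|, 26-neighborhood):
//' ng x 27 matrix, column j+1 = voxels with j dependent neighbors.
//' @noRd
// [[Rcpp::export(name = ".cpp_gldm_counts")]]
NumericMatrix cpp_gldm_counts(IntegerVector levels, IntegerVector dim, int ng,
                              int alpha) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 27);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int lv = levels[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        if (lv == 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int ii = i + dx, jj = j + dy, kk = k + dz;
              if (!in_grid(ii, jj, kk, nx, ny, nz)) continue;
              int lw = levels[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
              if (lw == 0) continue;
              if (std::abs(lw - lv) <= alpha) ++dep;
            }
        out(lv - 1, dep) += 1.0;
      }
  return out;
}

//' Neighborhood gray-tone difference sums: per level, s_i and the count n_i of
//' voxels having at least one in-ROI 26-neighbor.
//' @noRd
// [[Rcpp::export(name = ".cpp_ngtdm_sums")]]
List cpp_ngtdm_sums(IntegerVector levels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector s(ng), n(ng);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int lv = levels[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        if (lv == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int ii = i + dx, jj = j + dy, kk = k + dz;
              if (!in_grid(ii, jj, kk, nx, ny, nz)) continue;
              int lw = levels[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
              if (lw == 0) continue;
              sum += lw;
              ++cnt;
            }
        if (cnt > 0) {
          s[lv - 1] += std::fabs((double)lv - sum / cnt);
          n[lv - 1] += 1.0;
        }
      }
  return List::create(_["s"] = s, _["n"] = n);
}
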