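#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Large finite stand-in for +Inf so the parabola arithmetic stays well-defined.
static const double BIG = 1e30;
static const double SENTINEL = 1e300;

// 1D squared Euclidean distance transform (lower envelope of parabolas),
// sample positions x_q = q * w (physical spacing w).
static void edt1d(std::vector<double>& f, double w) {
  const int n = (int)f.size();
  if (n == 1) return;
  std::vector<double> d(n), z(n + 1);
  std::vector<int> v(n);
  int k = 0;
  v[0] = 0;
  z[0] = -SENTINEL;
  z[1] = SENTINEL;
  for (int q = 1; q < n; ++q) {
    double xq = q * w;
    double s;
    for (;;) {
      int p = v[k];
      double xp = p * w;
      s = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2.0 * (xq - xp));
      if (s <= z[k]) {
        --k;  // k >= 1 here: z[0] = -SENTINEL is below any finite s
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = SENTINEL;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

//' @noRd
// [[Rcpp::export(name = ".cpp_sq_edt")]]
NumericVector cpp_sq_edt(LogicalVector sites, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = sites[i] ? 0.0 : BIG;

  std::vector<double> line;
  // pass along x
  line.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) line[i] = out[base + i];
      edt1d(line, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = line[i];
    }
  // pass along y
  line.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j)
        line[j] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      edt1d(line, spacing[1]);
      for (int j = 0; j < ny; ++j)
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = line[j];
    }
  // pass along z
  line.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k)
        line[k] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      edt1d(line, spacing[2]);
      for (int k = 0; k < nz; ++k)
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = line[k];
    }
  return out;
}

//' For each point (row) of A, the distance to the nearest point of B.
//' @noRd
// [[Rcpp::export(name = ".cpp_min_dists")]]
NumericVector cpp_min_dists(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int a = 0; a < na; ++a) {
    double best = R_PosInf;
    const double ax = A(a, 0), ay = A(a, 1), az = A(a, 2);
    for (int b = 0; b < nb; ++b) {
      const double dx = ax - B(b, 0), dy = ay - B(b, 1), dz = az - B(b, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[a] = std::sqrt(best);
  }
  return out;
}

//' Connected-component labelling; connectivity 6 or 26.
//' @noRd
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);

  std::vector<std::array<int, 3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({{dx, dy, dz}});
      }

  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front();
      q.pop();
      int ci = (int)(cur % nx);
      int cj = (int)((cur / nx) % ny);
      int ck = (int)(cur / ((R_xlen_t)nx * ny));
      for (size_t o = 0; o < offs.size(); ++o) {
        int i = ci + offs[o][0], j = cj + offs[o][1], k = ck + offs[o][2];
        if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) continue;
        R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (mask[idx] && labels[idx] == 0) {
          labels[idx] = next;
          q.push(idx);
        }
      }
    }
  }
  return labels;
}
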