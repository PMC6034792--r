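#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// reflect index into [0, n) (scipy 'reflect': d c b a | a b c d)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export(name = ".sep_convolve_reflect")]]
NumericMatrix sep_convolve_reflect(const NumericMatrix& img,
                                   const NumericVector& krow,
                                   const NumericVector& kcol) {
  const int nr = img.nrow(), nc = img.ncol();
  const int rr = (krow.size() - 1) / 2, rc = (kcol.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // convolve along rows (vertical direction, varying row index) with krow
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = -rr; k <= rr; ++k)
        acc += krow[k + rr] * img(reflect_idx(i + k, nr), j);
      tmp(i, j) = acc;
    }
  // convolve along columns with kcol
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = -rc; k <= rc; ++k)
        acc += kcol[k + rc] * tmp(i, reflect_idx(j + k, nc));
      out(i, j) = acc;
    }
  return out;
}

// Connected-component labelling; connectivity 4 or 8. Labels assigned in
// row-major order of each component's first-encountered (top-left-most) pixel,
// so label 1's anchor precedes label 2's in row-major order.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  const int dx8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dy8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dx4[4] = {-1, 1, 0, 0};
  const int dy4[4] = {0, 0, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  const int* dx = (connectivity == 8) ? dx8 : dx4;
  const int* dy = (connectivity == 8) ? dy8 : dy4;
  std::queue<std::pair<int, int> > q;
  // row-major scan: iterate rows outer so "first pixel in row-major order" wins
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int k = 0; k < nn; ++k) {
          int ii = p.first + dx[k], jj = p.second + dy[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  return lab;
}

static void edt_1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  // Felzenszwalb & Huttenlocher lower-envelope of parabolas
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance to the nearest TRUE pixel.
// [[Rcpp::export(name = ".edt_squared")]]
NumericMatrix edt_squared(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e20;
  NumericMatrix d(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      d(i, j) = mask(i, j) ? 0.0 : INF;
  std::vector<double> f(std::max(nr, nc)), g(std::max(nr, nc));
  // along rows
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = d(i, j);
    edt_1d(f, g, nr);
    for (int i = 0; i < nr; ++i) d(i, j) = g[i];
  }
  // along columns
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = d(i, j);
    edt_1d(f, g, nc);
    for (int j = 0; j < nc; ++j) d(i, j) = g[j];
  }
  return d;
}
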