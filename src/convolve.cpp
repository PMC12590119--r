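#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Half-sample symmetric reflection (scipy.ndimage mode = "reflect"):
// indices ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Separable 2-D convolution with an odd-length symmetric 1-D kernel applied
// along both axes, reflect boundary. Used for pyramid blurring and for the
// local-magnitude normalization pool.
// [[Rcpp::export]]
NumericMatrix sep_conv2(const NumericMatrix& X, const NumericVector& k) {
  const int nr = X.nrow(), nc = X.ncol(), m = k.size();
  const int h = m / 2;
  std::vector<double> kk(k.begin(), k.end());
  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double* x = X.begin();
  double* t = tmp.begin();
  double* o = out.begin();

  // vertical pass (down each column, unit stride)
  for (int j = 0; j < nc; ++j) {
    const double* col = x + (size_t)j * nr;
    double* tcol = t + (size_t)j * nr;
    const int lo = h, hi = nr - (m - h - 1);
    for (int i = 0; i < std::min(lo, nr); ++i) {
      double acc = 0.0;
      for (int q = 0; q < m; ++q)
        acc += kk[q] * col[reflect_idx(i + q - h, nr)];
      tcol[i] = acc;
    }
    for (int i = lo; i < hi; ++i) {
      double acc = 0.0;
      const double* p = col + i - h;
      for (int q = 0; q < m; ++q) acc += kk[q] * p[q];
      tcol[i] = acc;
    }
    for (int i = std::max(hi, lo); i < nr; ++i) {
      double acc = 0.0;
      for (int q = 0; q < m; ++q)
        acc += kk[q] * col[reflect_idx(i + q - h, nr)];
      tcol[i] = acc;
    }
  }

  // horizontal pass: accumulate shifted columns (unit-stride inner loops)
  for (int j = 0; j < nc; ++j) {
    double* ocol = o + (size_t)j * nr;
    for (int q = 0; q < m; ++q) {
      const int src = reflect_idx(j + q - h, nc);
      const double w = kk[q];
      const double* tcol = t + (size_t)src * nr;
      if (q == 0)
        for (int i = 0; i < nr; ++i) ocol[i] = w * tcol[i];
      else
        for (int i = 0; i < nr; ++i) ocol[i] += w * tcol[i];
    }
  }
  return out;
}
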