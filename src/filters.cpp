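#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Reflection index into [0, n-1] (symmetric, edge duplicated).
static inline int reflect(int i, int n) {
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - i - 1;
  return i;
}

// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(NumericMatrix x, int kernel) {
  const int m = x.nrow(), n = x.ncol();
  const int r = (kernel - 1) / 2;
  const int k2 = kernel * kernel;
  NumericMatrix out(m, n);
  std::vector<double> win(k2);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) {
      int p = 0;
      for (int dj = -r; dj <= r; ++dj) {
        const int jj = reflect(j + dj, n);
        for (int di = -r; di <= r; ++di) {
          win[p++] = x(reflect(i + di, m), jj);
        }
      }
      std::nth_element(win.begin(), win.begin() + k2 / 2, win.end());
      double med = win[k2 / 2];
      if (k2 % 2 == 0) {
        std::nth_element(win.begin(), win.begin() + k2 / 2 - 1,
                         win.begin() + k2 / 2);
        med = 0.5 * (med + win[k2 / 2 - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}
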