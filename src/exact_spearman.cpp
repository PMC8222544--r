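#include <Rcpp.h>
#include <vector>
#include <cmath>

// Exact two-sided permutation p-value for the Spearman coefficient
// (Pearson on average ranks), enumerating all n! permutations of the
// y-ranks with Heap's algorithm and an O(1) incremental update of the
// cross-product sum. Ranks are multiples of 0.5, so all sums are exactly
// representable and the comparison needs only a tiny absolute guard.
// Intended for n <= 10 (10! = 3,628,800 permutations).

// [[Rcpp::export]]
double exact_spearman_pvalue(Rcpp::NumericVector rx, Rcpp::NumericVector ry) {
  const int n = rx.size();
  if (n != ry.size()) Rcpp::stop("rank vectors must have equal length");
  if (n < 2) return NA_REAL;
  if (n > 10) Rcpp::stop("exact permutation supported only for n <= 10");

  std::vector<double> x(rx.begin(), rx.end());
  std::vector<double> y(ry.begin(), ry.end());

  double mx = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double ssx = 0.0, ssy = 0.0, S = 0.0;
  for (int i = 0; i < n; ++i) {
    ssx += (x[i] - mx) * (x[i] - mx);
    ssy += (y[i] - my) * (y[i] - my);
    S += x[i] * y[i];
  }
  if (ssx <= 0.0 || ssy <= 0.0) return NA_REAL;

  const double centre = n * mx * my;
  const double target = std::fabs(S - centre) - 1e-9;

  long long count = 0, total = 0;
  std::vector<int> c(n, 0);
  if (std::fabs(S - centre) >= target) ++count;
  ++total;
  int i = 0;
  while (i < n) {
    if (c[i] < i) {
      const int a = (i % 2 == 0) ? 0 : c[i];
      // swap y[a] <-> y[i]; update S incrementally
      S += x[a] * (y[i] - y[a]) + x[i] * (y[a] - y[i]);
      const double tmp = y[a]; y[a] = y[i]; y[i] = tmp;
      if (std::fabs(S - centre) >= target) ++count;
      ++total;
      ++c[i];
      i = 0;
    } else {
      c[i++] = 0;
    }
  }
  return static_cast<double>(count) / static_cast<double>(total);
}
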