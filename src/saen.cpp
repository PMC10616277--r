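#include <Rcpp.h>
#include <cmath>
#include <algorithm>

// Template-match counts for sample entropy with time delay.
// z: (z-normalized) series of increments, length L.
// Templates start at i = 0..N-1 with N = L - m*delta, so that every
// length-m template can be extended to length m+1 (Richman-Moorman
// convention: B and A are counted over the same template set).
// A pair matches at length m when the Chebyshev distance over the m
// delayed coordinates is strictly below r.  Self-matches are excluded.
// [[Rcpp::export]]
Rcpp::NumericVector saen_counts(Rcpp::NumericVector z, int m, double r,
                                int delta) {
  const int L = z.size();
  const int N = L - m * delta;
  double A = 0.0, B = 0.0;
  if (N < 2)
    return Rcpp::NumericVector::create(Rcpp::Named("B") = 0.0,
                                       Rcpp::Named("A") = 0.0);
  const double *x = z.begin();
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      bool ok = true;
      double dmax = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k * delta] - x[j + k * delta]);
        if (d > dmax) dmax = d;
        if (dmax >= r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double d = std::fabs(x[i + m * delta] - x[j + m * delta]);
      if (std::max(dmax, d) < r) A += 1.0;
    }
  }
  return Rcpp::NumericVector::create(Rcpp::Named("B") = B,
                                     Rcpp::Named("A") = A);
}
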