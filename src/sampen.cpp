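#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy.
//
// Counts pairs (i, j), i < j, over the N - m templates of length m whose
// Chebyshev distance is <= r (count_m), and how many of those still match
// when extended by one point (count_m1). Self-matches are excluded by
// construction. Both counts use the same i, j range so the conditional
// probability ratio is well defined.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of length-(m+1)-extensible templates
  double cm = 0.0, cm1 = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        d = std::fabs(x[i + k] - x[j + k]);
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      cm += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) cm1 += 1.0;
    }
  }
  return NumericVector::create(cm, cm1);
}
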