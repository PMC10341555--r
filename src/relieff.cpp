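// Relief-F inner loop over pre-scaled features. The R wrapper owns the
// min-max scaling, neighbor-count clipping, prior estimation and the RNG
// draws; this routine just applies the hit/miss updates deterministically.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector relieff_core(NumericMatrix Xs, IntegerVector y,
                           IntegerVector draws, int k,
                           NumericVector prior, IntegerVector classes) {
  const int n = Xs.nrow(), p = Xs.ncol();
  const int m = draws.size(), nc = classes.size();
  std::vector<double> Xv(Xs.begin(), Xs.end());  // column-major
  std::vector<std::vector<int>> by_class(nc);
  std::vector<int> class_of(n);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < nc; ++c)
      if (y[i] == classes[c]) { by_class[c].push_back(i); class_of[i] = c; }
  }

  NumericVector W(p);
  std::vector<double> d(n);
  std::vector<int> cand;
  cand.reserve(n);

  for (int it = 0; it < m; ++it) {
    const int r = draws[it] - 1;  // R is 1-based
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < p; ++j)
        s += std::fabs(Xv[(size_t)j * n + i] - Xv[(size_t)j * n + r]);
      d[i] = s;
    }
    const int cr = class_of[r];
    for (int c = 0; c < nc; ++c) {
      cand.assign(by_class[c].begin(), by_class[c].end());
      if (c == cr) cand.erase(std::remove(cand.begin(), cand.end(), r), cand.end());
      const int kk = std::min<int>(k, (int)cand.size());
      if (kk < (int)cand.size()) {
        std::nth_element(cand.begin(), cand.begin() + kk, cand.end(),
                         [&](int a, int b) {
                           return d[a] < d[b] || (d[a] == d[b] && a < b);
                         });
      }
      const double factor =
          (c == cr) ? -1.0 : prior[c] / (1.0 - prior[cr]);
      for (int qi = 0; qi < kk; ++qi) {
        const int q = cand[qi];
        if (d[q] == 0.0) continue;  // duplicate sample: skip, no div by 0
        const double scale = factor / (m * d[q]);
        for (int j = 0; j < p; ++j)
          W[j] += scale * std::fabs(Xv[(size_t)j * n + r] - Xv[(size_t)j * n + q]);
      }
    }
  }
  return W;
}
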