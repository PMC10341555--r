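// Binary-classification tree ensembles (random forest and extremely
// randomized trees) with Gini impurity and mean-decrease-impurity feature
// importances. Self-contained so the package has no dependency on an
// external ensemble implementation; deterministic for a fixed seed.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

// splitmix64: stable across platforms, one stream per tree
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) { next(); next(); }
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int unif_int(int n) { return (int)(unif() * n) % n; }
};

struct Tree {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> leaf_p;   // class-1 probability at leaf
  int add_node() {
    feature.push_back(-1); thr.push_back(0.0);
    left.push_back(-1); right.push_back(-1); leaf_p.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

struct NodeJob { int lo, hi, node; };

inline double gini(double n1, double n) {
  if (n <= 0.0) return 0.0;
  double p1 = n1 / n;
  return 2.0 * p1 * (1.0 - p1);
}

}  // namespace

// [[Rcpp::export]]
List forest_fit(NumericMatrix X, IntegerVector y, NumericMatrix Xtest,
                int n_trees, int mtry, bool bootstrap, bool random_split,
                int min_leaf, double seed) {
  const int n = X.nrow(), p = X.ncol();
  const int ntest = Xtest.nrow();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  // column-major copy for tight inner loops
  std::vector<double> Xv(X.begin(), X.end());
  std::vector<int> yv(y.begin(), y.end());

  NumericVector importance(p);
  NumericVector prob(ntest);
  std::vector<double> imp_tree(p);
  std::vector<int> feat_pool(p);
  std::vector<int> idx(n), ord(n);
  std::vector<double> colv(n);

  for (int t = 0; t < n_trees; ++t) {
    Rng rng((uint64_t)seed * 2654435761ULL + 0x9E3779B9ULL * (uint64_t)(t + 1));
    if (bootstrap) {
      for (int i = 0; i < n; ++i) idx[i] = rng.unif_int(n);
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    std::fill(imp_tree.begin(), imp_tree.end(), 0.0);

    Tree tree;
    std::vector<NodeJob> stack;
    tree.add_node();
    stack.push_back({0, n, 0});

    while (!stack.empty()) {
      NodeJob job = stack.back(); stack.pop_back();
      const int lo = job.lo, hi = job.hi, node = job.node;
      const int nn = hi - lo;
      double n1 = 0.0;
      for (int i = lo; i < hi; ++i) n1 += yv[idx[i]];
      const double node_imp = gini(n1, nn);
      if (nn < 2 * min_leaf || nn < 2 || n1 == 0.0 || n1 == (double)nn) {
        tree.leaf_p[node] = n1 / nn;
        continue;
      }

      for (int j = 0; j < p; ++j) feat_pool[j] = j;
      int best_f = -1;
      double best_thr = 0.0, best_dec = 1e-12;

      for (int c = 0; c < mtry; ++c) {
        int pick = c + rng.unif_int(p - c);
        std::swap(feat_pool[c], feat_pool[pick]);
        const int f = feat_pool[c];
        const double* col = &Xv[(size_t)f * n];

        if (random_split) {
          double vmin = col[idx[lo]], vmax = vmin;
          for (int i = lo + 1; i < hi; ++i) {
            double v = col[idx[i]];
            if (v < vmin) vmin = v;
            if (v > vmax) vmax = v;
          }
          if (vmin == vmax) continue;
          double cut = vmin + rng.unif() * (vmax - vmin);
          double nl = 0.0, nl1 = 0.0;
          for (int i = lo; i < hi; ++i) {
            if (col[idx[i]] <= cut) { nl += 1.0; nl1 += yv[idx[i]]; }
          }
          double nr = nn - nl;
          if (nl < min_leaf || nr < min_leaf) continue;
          double dec = node_imp - (nl / nn) * gini(nl1, nl)
                                - (nr / nn) * gini(n1 - nl1, nr);
          if (dec > best_dec) { best_dec = dec; best_f = f; best_thr = cut; }
        } else {
          for (int i = 0; i < nn; ++i) {
            ord[i] = idx[lo + i];
            colv[i] = col[idx[lo + i]];
          }
          std::sort(ord.begin(), ord.begin() + nn,
                    [&](int a, int b) { return col[a] < col[b]; });
          if (col[ord[0]] == col[ord[nn - 1]]) continue;
          double nl1 = 0.0;
          for (int i = 0; i < nn - 1; ++i) {
            nl1 += yv[ord[i]];
            double vi = col[ord[i]], vj = col[ord[i + 1]];
            if (vi == vj) continue;
            double nl = i + 1.0, nr = nn - nl;
            if (nl < min_leaf || nr < min_leaf) continue;
            double dec = node_imp - (nl / nn) * gini(nl1, nl)
                                  - (nr / nn) * gini(n1 - nl1, nr);
            if (dec > best_dec) {
              best_dec = dec; best_f = f; best_thr = 0.5 * (vi + vj);
            }
          }
        }
      }

      if (best_f < 0) {
        tree.leaf_p[node] = n1 / nn;
        continue;
      }

      const double* bcol = &Xv[(size_t)best_f * n];
      int mid = lo;
      for (int i = lo; i < hi; ++i) {
        if (bcol[idx[i]] <= best_thr) std::swap(idx[i], idx[mid++]);
      }
      if (mid == lo || mid == hi) {  // numerically degenerate
        tree.leaf_p[node] = n1 / nn;
        continue;
      }
      imp_tree[best_f] += ((double)nn / n) * best_dec;

      int l = tree.add_node();
      int r = tree.add_node();
      tree.feature[node] = best_f; tree.thr[node] = best_thr;
      tree.left[node] = l; tree.right[node] = r;
      stack.push_back({lo, mid, l});
      stack.push_back({mid, hi, r});
    }

    for (int j = 0; j < p; ++j) importance[j] += imp_tree[j] / n_trees;

    for (int i = 0; i < ntest; ++i) {
      int node = 0;
      while (tree.feature[node] >= 0) {
        node = (Xtest(i, tree.feature[node]) <= tree.thr[node])
                 ? tree.left[node] : tree.right[node];
      }
      prob[i] += tree.leaf_p[node] / n_trees;
    }
  }

  return List::create(_["importance"] = importance, _["prob"] = prob);
}
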