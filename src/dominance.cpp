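#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Dense ranks of x against its sorted unique values (1-based).
static std::vector<int> dense_rank(const NumericVector& x) {
  std::vector<double> u(x.begin(), x.end());
  std::sort(u.begin(), u.end());
  u.erase(std::unique(u.begin(), u.end()), u.end());
  std::vector<int> r(x.size());
  for (int i = 0; i < x.size(); ++i)
    r[i] = (int)(std::lower_bound(u.begin(), u.end(), x[i]) - u.begin()) + 1;
  return r;
}

// Indices 0..n-1 ordered by key ascending (stable).
static std::vector<int> order_by(const NumericVector& key) {
  std::vector<int> idx(key.size());
  for (int i = 0; i < (int)idx.size(); ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return key[a] < key[b]; });
  return idx;
}

// Joint dominance counts: out[k] = #{ m : x[m] <= x[k] && y[m] <= y[k] },
// both comparisons inclusive, so out[k] >= 1 (k counts itself).
// Sweep in y order, tied-y groups inserted before any member queries, with a
// Fenwick tree over dense x ranks: O(n log n).
// [[Rcpp::export]]
IntegerVector dominance_count(NumericVector x, NumericVector y) {
  int n = x.size();
  IntegerVector out(n);
  std::vector<int> rx = dense_rank(x);
  int m = 0;
  for (int i = 0; i < n; ++i) m = std::max(m, rx[i]);
  std::vector<int> tree(m + 1, 0);
  auto update = [&](int i) { for (; i <= m; i += i & -i) tree[i]++; };
  auto query  = [&](int i) { int s = 0; for (; i > 0; i -= i & -i) s += tree[i]; return s; };

  std::vector<int> idx = order_by(y);
  int g = 0;
  while (g < n) {
    int h = g;
    while (h < n && y[idx[h]] == y[idx[g]]) ++h;
    for (int t = g; t < h; ++t) update(rx[idx[t]]);
    for (int t = g; t < h; ++t) out[idx[t]] = query(rx[idx[t]]);
    g = h;
  }
  return out;
}

// Dominated running maximum: out[k] = max{ v[m] : x[m] <= x[k] && y[m] <= y[k] }.
// Same sweep with a max-Fenwick tree (prefix maxima only, which suffices).
// [[Rcpp::export]]
NumericVector dominance_max(NumericVector v, NumericVector x, NumericVector y) {
  int n = v.size();
  NumericVector out(n);
  std::vector<int> rx = dense_rank(x);
  int m = 0;
  for (int i = 0; i < n; ++i) m = std::max(m, rx[i]);
  std::vector<double> tree(m + 1, R_NegInf);
  auto update = [&](int i, double val) {
    for (; i <= m; i += i & -i) tree[i] = std::max(tree[i], val);
  };
  auto query = [&](int i) {
    double s = R_NegInf;
    for (; i > 0; i -= i & -i) s = std::max(s, tree[i]);
    return s;
  };

  std::vector<int> idx = order_by(y);
  int g = 0;
  while (g < n) {
    int h = g;
    while (h < n && y[idx[h]] == y[idx[g]]) ++h;
    for (int t = g; t < h; ++t) update(rx[idx[t]], v[idx[t]]);
    for (int t = g; t < h; ++t) out[idx[t]] = query(rx[idx[t]]);
    g = h;
  }
  return out;
}
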