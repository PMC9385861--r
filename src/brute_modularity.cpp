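// Exhaustive Newman-Girvan modularity maximization over all set partitions
// of a small node set, enumerated as restricted growth strings. Serves as
// the independent oracle for the greedy optimizer.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List brute_modularity_cpp(int n, IntegerVector from, IntegerVector to) {
  int m = from.size();
  if (m == 0) stop("graph has no edges");
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) {
    deg[from[e]]++;
    deg[to[e]]++;
  }
  std::vector<int> a(n, 0);   // restricted growth string
  std::vector<int> best(n, 0);
  double bestQ = -1e9;
  const double twoM = 2.0 * m;

  while (true) {
    // Q = sum_c (e_c / m - (d_c / 2m)^2)
    std::vector<double> ein(n, 0.0), dsum(n, 0.0);
    for (int e = 0; e < m; ++e)
      if (a[from[e]] == a[to[e]]) ein[a[from[e]]] += 1.0;
    for (int v = 0; v < n; ++v) dsum[a[v]] += deg[v];
    double q = 0.0;
    for (int c = 0; c < n; ++c)
      q += ein[c] / m - (dsum[c] / twoM) * (dsum[c] / twoM);
    if (q > bestQ) {
      bestQ = q;
      best = a;
    }
    // next restricted growth string: a[i] <= 1 + max(a[0..i-1])
    int i = n - 1;
    for (; i > 0; --i) {
      int maxPrev = 0;
      for (int j = 0; j < i; ++j) maxPrev = std::max(maxPrev, a[j]);
      if (a[i] <= maxPrev) break;
    }
    if (i == 0) break;
    a[i]++;
    for (int j = i + 1; j < n; ++j) a[j] = 0;
  }
  return List::create(Named("q") = bestQ,
                      Named("membership") = IntegerVector(best.begin(),
                                                          best.end()));
}
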