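#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving edge switching on a bipartite edge list.
// tf, prom are 1-based integer codes; attempts swaps are proposed, each
// picking two edges uniformly and exchanging their promoter endpoints iff
// neither resulting edge already exists. Uses R's RNG so set.seed() makes
// the result reproducible.
// [[Rcpp::export]]
IntegerMatrix edge_switch_cpp(IntegerVector tf, IntegerVector prom,
                              int n_prom, int attempts) {
  int m = tf.size();
  std::vector<int> t(tf.begin(), tf.end());
  std::vector<int> p(prom.begin(), prom.end());
  std::unordered_set<long long> present;
  present.reserve(2 * m);
  const long long stride = (long long)n_prom + 1;
  for (int i = 0; i < m; ++i)
    present.insert((long long)t[i] * stride + p[i]);
  for (int it = 0; it < attempts; ++it) {
    int i = (int)(unif_rand() * m); if (i >= m) i = m - 1;
    int j = (int)(unif_rand() * m); if (j >= m) j = m - 1;
    if (i == j) continue;
    if (t[i] == t[j] || p[i] == p[j]) continue;
    long long k1 = (long long)t[i] * stride + p[j];
    long long k2 = (long long)t[j] * stride + p[i];
    if (present.count(k1) || present.count(k2)) continue;
    present.erase((long long)t[i] * stride + p[i]);
    present.erase((long long)t[j] * stride + p[j]);
    int tmp = p[i]; p[i] = p[j]; p[j] = tmp;
    present.insert(k1);
    present.insert(k2);
  }
  IntegerMatrix out(m, 2);
  for (int i = 0; i < m; ++i) { out(i, 0) = t[i]; out(i, 1) = p[i]; }
  return out;
}
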