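#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// tie-corrected standardized rank-sum statistic for the values indexed by
// ga (group a) and gb (group b); midranks computed on the pooled pair
static double pair_stat(const std::vector<double>& vals,
                        const std::vector<int>& ga,
                        const std::vector<int>& gb) {
  const int n1 = ga.size(), n2 = gb.size(), N = n1 + n2;
  std::vector<std::pair<double, int>> v(N); // (value, 0 if group a else 1)
  for (int i = 0; i < n1; ++i) v[i] = {vals[ga[i]], 0};
  for (int i = 0; i < n2; ++i) v[n1 + i] = {vals[gb[i]], 1};
  std::sort(v.begin(), v.end());
  double W = 0.0, sumr2 = 0.0;
  int i = 0;
  while (i < N) {
    int j = i;
    while (j + 1 < N && v[j + 1].first == v[i].first) ++j;
    double midrank = 0.5 * (i + j) + 1.0;
    for (int t = i; t <= j; ++t) {
      sumr2 += midrank * midrank;
      if (v[t].second == 0) W += midrank;
    }
    i = j + 1;
  }
  double E = n1 * (N + 1) / 2.0;
  double V = (double)n1 * n2 / ((double)N * (N - 1)) *
             (sumr2 - N * (N + 1.0) * (N + 1.0) / 4.0);
  if (V <= 0.0) return 0.0;
  return (W - E) / std::sqrt(V);
}

// recursively enumerate partitions of indices `pool` into groups of sizes
// `sizes`; for each partition accumulate whether max_pair |T*| >= obs[p]
static void enumerate(const std::vector<double>& vals,
                      const IntegerVector& sizes,
                      std::vector<int>& pool, size_t pool_pos,
                      std::vector<std::vector<int>>& groups, int gi,
                      const IntegerMatrix& pairs,
                      const NumericVector& obs,
                      std::vector<double>& count, double& total) {
  const int k = sizes.size();
  if (gi == k - 1) {
    // last group = remaining pool
    std::vector<int>& last = groups[k - 1];
    last.clear();
    std::vector<bool> used(pool.size(), false);
    for (int g = 0; g < k - 1; ++g)
      for (int idx : groups[g])
        for (size_t t = 0; t < pool.size(); ++t)
          if (!used[t] && pool[t] == idx) { used[t] = true; break; }
    for (size_t t = 0; t < pool.size(); ++t)
      if (!used[t]) last.push_back(pool[t]);
    double maxT = 0.0;
    std::vector<double> ts(pairs.ncol());
    for (int p = 0; p < pairs.ncol(); ++p) {
      ts[p] = std::fabs(pair_stat(vals, groups[pairs(0, p)],
                                  groups[pairs(1, p)]));
      if (ts[p] > maxT) maxT = ts[p];
    }
    total += 1.0;
    for (int p = 0; p < pairs.ncol(); ++p)
      if (maxT >= obs[p] - 1e-9) count[p] += 1.0;
    return;
  }
  // choose sizes[gi] elements from pool positions >= pool_pos that are free
  // use combination enumeration over the free positions
  std::vector<int> freepos;
  std::vector<bool> used(pool.size(), false);
  for (int g = 0; g < gi; ++g)
    for (int idx : groups[g])
      for (size_t t = 0; t < pool.size(); ++t)
        if (!used[t] && pool[t] == idx) { used[t] = true; break; }
  for (size_t t = 0; t < pool.size(); ++t)
    if (!used[t]) freepos.push_back((int)t);
  const int m = freepos.size(), r = sizes[gi];
  std::vector<int> comb(r);
  for (int i = 0; i < r; ++i) comb[i] = i;
  // to avoid counting permutations of identical later groups as distinct is
  // unnecessary: p-values are ratios, duplication cancels out
  while (true) {
    groups[gi].clear();
    for (int i = 0; i < r; ++i) groups[gi].push_back(pool[freepos[comb[i]]]);
    enumerate(vals, sizes, pool, pool_pos, groups, gi + 1, pairs, obs,
              count, total);
    int i = r - 1;
    while (i >= 0 && comb[i] == m - r + i) --i;
    if (i < 0) break;
    ++comb[i];
    for (int j = i + 1; j < r; ++j) comb[j] = comb[j - 1] + 1;
  }
}

// [[Rcpp::export]]
NumericVector steel_dwass_exact_cpp(NumericVector values,
                                    IntegerVector sizes,
                                    IntegerMatrix pairs0,
                                    NumericVector obs) {
  std::vector<double> vals(values.begin(), values.end());
  std::vector<int> pool(values.size());
  for (size_t i = 0; i < pool.size(); ++i) pool[i] = (int)i;
  std::vector<std::vector<int>> groups(sizes.size());
  std::vector<double> count(pairs0.ncol(), 0.0);
  double total = 0.0;
  enumerate(vals, sizes, pool, 0, groups, 0, pairs0, obs, count, total);
  NumericVector out(pairs0.ncol());
  for (int p = 0; p < pairs0.ncol(); ++p) out[p] = count[p] / total;
  return out;
}
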