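#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Markov-chain Monte Carlo estimate of the exact Hardy-Weinberg
// probability-test p-value, conditional on allele counts.
//
// The chain walks on the pairing of the 2n gene copies: each step proposes
// swapping the alleles at two uniformly chosen copy positions. The uniform
// distribution over pairings is stationary for this symmetric walk and
// induces exactly the conditional null P(table) proportional to
// 2^H / prod n_ij!, so every proposal is accepted (the Guo-Thompson switch
// chain in its always-accept form). The p-value is the visited fraction of
// tables no more probable than the observed one; its Monte-Carlo standard
// error comes from the between-batch variance.

static inline int cell(int i, int j, int k) {
  // upper-triangle index, i <= j
  return i * k + j;
}

// [[Rcpp::export(name = ".hwe_chain_cpp")]]
List hwe_chain_cpp(IntegerMatrix counts, int dememorization, int batches,
                   int iter_per_batch) {
  int k = counts.nrow();
  if (counts.ncol() != k) stop("counts must be square");
  // build gene-copy vector paired as (0,1), (2,3), ...
  std::vector<int> g;
  std::vector<int> cnt(k * k, 0);
  for (int i = 0; i < k; ++i)
    for (int j = i; j < k; ++j) {
      int c = (i == j) ? counts(i, j) : counts(i, j) + counts(j, i);
      cnt[cell(i, j, k)] = c;
      for (int t = 0; t < c; ++t) { g.push_back(i); g.push_back(j); }
    }
  int n2 = g.size();
  int n = n2 / 2;
  if (n < 1) stop("empty genotype table");
  // log-factorial lookup
  std::vector<double> lf(n + 1);
  lf[0] = 0.0;
  for (int i = 1; i <= n; ++i) lf[i] = lf[i - 1] + std::log((double)i);
  const double LOG2 = std::log(2.0);
  int H = 0;
  double sumlf = 0.0;
  for (int i = 0; i < k; ++i)
    for (int j = i; j < k; ++j) {
      int c = cnt[cell(i, j, k)];
      sumlf += lf[c];
      if (i != j) H += c;
    }
  double S_obs = H * LOG2 - sumlf;
  const double eps = 1e-9;

  // incremental cell updates
  auto dec = [&](int a, int b) {
    int i = a < b ? a : b, j = a < b ? b : a;
    int &c = cnt[cell(i, j, k)];
    sumlf += lf[c - 1] - lf[c];
    --c;
    if (i != j) --H;
  };
  auto inc = [&](int a, int b) {
    int i = a < b ? a : b, j = a < b ? b : a;
    int &c = cnt[cell(i, j, k)];
    sumlf += lf[c + 1] - lf[c];
    ++c;
    if (i != j) ++H;
  };
  auto step = [&]() {
    int u = (int)(unif_rand() * n2); if (u >= n2) u = n2 - 1;
    int v = (int)(unif_rand() * n2); if (v >= n2) v = n2 - 1;
    if (u == v || (u / 2) == (v / 2)) return;
    int a = g[u], b = g[v];
    if (a == b) { g[u] = b; g[v] = a; return; }
    int ap = g[u ^ 1], bp = g[v ^ 1];
    dec(a, ap); dec(b, bp);
    inc(b, ap); inc(a, bp);
    g[u] = b; g[v] = a;
  };

  for (int s = 0; s < dememorization; ++s) step();

  NumericVector batch_means(batches);
  for (int b = 0; b < batches; ++b) {
    // refresh sumlf/H from counts to stop floating-point drift
    H = 0; sumlf = 0.0;
    for (int i = 0; i < k; ++i)
      for (int j = i; j < k; ++j) {
        int c = cnt[cell(i, j, k)];
        sumlf += lf[c];
        if (i != j) H += c;
      }
    long hits = 0;
    for (int s = 0; s < iter_per_batch; ++s) {
      step();
      double S = H * LOG2 - sumlf;
      if (S <= S_obs + eps) ++hits;
    }
    batch_means[b] = (double)hits / iter_per_batch;
  }
  double p = mean(batch_means);
  double se = 0.0;
  if (batches > 1) se = sd(batch_means) / std::sqrt((double)batches);
  return List::create(_["p"] = p, _["mc_se"] = se,
                      _["S_obs"] = S_obs, _["batch_means"] = batch_means);
}
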