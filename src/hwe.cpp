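#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact conditional Hardy-Weinberg test utilities.
//
// A genotype table with counts g[i][j] (i <= j) and fixed allele counts
// m[i] has conditional probability
//   P = n! * prod_i m_i! * 2^h / ((2n)! * prod_{i<=j} g_ij!)
// with h the number of heterozygotes. The p-value sums P over all tables
// (same allele counts) whose probability does not exceed the observed
// table's.

static double table_var_lp(const std::vector<int>& g, int k) {
  // variable part of log P: h*log(2) - sum lgamma(g+1)
  double lp = 0.0;
  int idx = 0;
  for (int i = 0; i < k; ++i) {
    for (int j = i; j < k; ++j, ++idx) {
      lp -= std::lgamma((double)g[idx] + 1.0);
      if (i != j) lp += g[idx] * std::log(2.0);
    }
  }
  return lp;
}

struct EnumState {
  int k;
  double const_lp;   // n! prod m_i! / (2n)! on log scale
  double obs_lp;     // full log prob of observed table
  double tol;
  double psum;       // sum of P over tables with lp <= obs_lp + tol
  double total;      // sum of P over all tables (check, ~1)
  long long count;
  long long bound;
  bool aborted;
};

// recurse over cells in row-major upper-triangle order
static void enum_rec(EnumState& st, std::vector<int>& rem, int i, int j,
                     double lp_acc) {
  if (st.aborted) return;
  int k = st.k;
  if (i == k) {
    ++st.count;
    if (st.count > st.bound) { st.aborted = true; return; }
    double lp = st.const_lp + lp_acc;
    double p = std::exp(lp);
    st.total += p;
    if (lp <= st.obs_lp + st.tol) st.psum += p;
    return;
  }
  if (j == k) { // row i finished; rem[i] must be zero by construction
    enum_rec(st, rem, i + 1, i + 1, lp_acc);
    return;
  }
  if (i == j && j == k - 1 && i == k - 1) {
    // very last cell (k-1,k-1): forced g = rem/2
    if (rem[i] % 2 != 0) return;
    int g = rem[i] / 2;
    rem[i] = 0;
    enum_rec(st, rem, i, k, lp_acc - std::lgamma((double)g + 1.0));
    rem[i] = 2 * g;
    return;
  }
  if (j == k - 1 && i < k - 1) {
    // last off-diagonal cell of row i: forced g = rem[i]
    int g = rem[i];
    if (g > rem[j]) return;
    rem[i] -= g; rem[j] -= g;
    enum_rec(st, rem, i, k, lp_acc + g * std::log(2.0)
                            - std::lgamma((double)g + 1.0));
    rem[i] += g; rem[j] += g;
    return;
  }
  if (i == j) {
    int gmax = rem[i] / 2;
    for (int g = 0; g <= gmax; ++g) {
      rem[i] -= 2 * g;
      enum_rec(st, rem, i, j + 1, lp_acc - std::lgamma((double)g + 1.0));
      rem[i] += 2 * g;
      if (st.aborted) return;
    }
  } else {
    int gmax = std::min(rem[i], rem[j]);
    for (int g = 0; g <= gmax; ++g) {
      rem[i] -= g; rem[j] -= g;
      enum_rec(st, rem, i, j + 1, lp_acc + g * std::log(2.0)
                                  - std::lgamma((double)g + 1.0));
      rem[i] += g; rem[j] += g;
      if (st.aborted) return;
    }
  }
}

// [[Rcpp::export(name = ".hwe_enumerate_cpp")]]
List hwe_enumerate_cpp(IntegerVector allele_counts, IntegerVector obs_table,
                       double bound) {
  int k = allele_counts.size();
  int n2 = 0;
  for (int i = 0; i < k; ++i) n2 += allele_counts[i];
  int n = n2 / 2;
  double const_lp = std::lgamma(n + 1.0) - std::lgamma(n2 + 1.0);
  for (int i = 0; i < k; ++i) const_lp += std::lgamma(allele_counts[i] + 1.0);

  std::vector<int> obs(obs_table.begin(), obs_table.end());
  double obs_lp = const_lp + table_var_lp(obs, k);

  EnumState st;
  st.k = k; st.const_lp = const_lp; st.obs_lp = obs_lp;
  st.tol = 1e-9 * (1.0 + std::fabs(obs_lp));
  st.psum = 0.0; st.total = 0.0; st.count = 0;
  st.bound = (long long)bound; st.aborted = false;
  std::vector<int> rem(allele_counts.begin(), allele_counts.end());
  enum_rec(st, rem, 0, 0, 0.0);

  return List::create(_["aborted"] = st.aborted,
                      _["p_value"] = st.psum / st.total,
                      _["total"] = st.total,
                      _["n_tables"] = (double)st.count);
}

// [[Rcpp::export(name = ".hwe_mc_cpp")]]
List hwe_mc_cpp(IntegerVector allele_counts, IntegerVector obs_table,
                int n_sim) {
  int k = allele_counts.size();
  std::vector<int> copies;
  for (int i = 0; i < k; ++i)
    for (int c = 0; c < allele_counts[i]; ++c) copies.push_back(i);
  int n2 = copies.size();
  std::vector<int> obs(obs_table.begin(), obs_table.end());
  double obs_lp = table_var_lp(obs, k);
  double tol = 1e-9 * (1.0 + std::fabs(obs_lp));

  GetRNGstate();
  int hits = 0;
  std::vector<int> g(k * (k + 1) / 2);
  // cell index for pair (i,j), i<=j, in the row-major triangle order
  std::vector<std::vector<int>> cell(k, std::vector<int>(k));
  {
    int idx = 0;
    for (int i = 0; i < k; ++i)
      for (int j = i; j < k; ++j, ++idx) { cell[i][j] = idx; cell[j][i] = idx; }
  }
  for (int b = 0; b < n_sim; ++b) {
    for (int i = n2 - 1; i > 0; --i) { // Fisher-Yates with R's RNG
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(copies[i], copies[j]);
    }
    std::fill(g.begin(), g.end(), 0);
    for (int i = 0; i < n2; i += 2) g[cell[copies[i]][copies[i + 1]]]++;
    double lp = table_var_lp(g, k);
    if (lp <= obs_lp + tol) ++hits;
  }
  PutRNGstate();
  return List::create(_["p_value"] = (hits + 1.0) / (n_sim + 1.0),
                      _["n_sim"] = n_sim);
}
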