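#include <Rcpp.h>
using namespace Rcpp;

// Optimal-matching edit distance between two integer-coded state sequences.
// sc is the (symmetric) substitution cost matrix over 1-based state codes;
// insertions and deletions both cost `indel`. Classic O(nm) two-row DP.
// [[Rcpp::export]]
double om_dp_cpp(IntegerVector s1, IntegerVector s2, NumericMatrix sc,
                 double indel) {
  int n = s1.size(), m = s2.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j * indel;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * indel;
    int a = s1[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      double sub = prev[j - 1] + sc(a, s2[j - 1] - 1);
      double del = prev[j] + indel;
      double ins = cur[j - 1] + indel;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// All pairwise OM distances; upper triangle computed once, mirrored.
// [[Rcpp::export]]
NumericMatrix om_pairwise_cpp(List seqs, NumericMatrix sc, double indel) {
  int n = seqs.size();
  NumericMatrix D(n, n);
  std::vector<IntegerVector> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<IntegerVector>(seqs[i]);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = om_dp_cpp(ss[i], ss[j], sc, indel);
      D(i, j) = d;
      D(j, i) = d;
    }
  return D;
}
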