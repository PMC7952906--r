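// Pairwise global-alignment match scores. With unit match score and no
// mismatch or gap penalties the optimal global alignment score equals the
// longest-common-subsequence length, computed here by dynamic programming.
#include <Rcpp.h>

static int lcs_len(const Rcpp::IntegerVector& a, const Rcpp::IntegerVector& b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".cpp_lcs_matrix")]]
Rcpp::IntegerMatrix cpp_lcs_matrix(Rcpp::List seqs) {
  const int n = seqs.size();
  Rcpp::IntegerMatrix S(n, n);
  std::vector<Rcpp::IntegerVector> v(n);
  for (int i = 0; i < n; ++i) v[i] = Rcpp::as<Rcpp::IntegerVector>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    S(i, i) = v[i].size();
    for (int j = i + 1; j < n; ++j) {
      int s = lcs_len(v[i], v[j]);
      S(i, j) = s; S(j, i) = s;
    }
  }
  return S;
}
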