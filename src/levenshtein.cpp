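#include <Rcpp.h>
#include <string>
#include <vector>

// Unit-cost edit distance by the classic dynamic-programming recurrence:
// LD(p,0) = p, LD(0,q) = q; otherwise min of delete/insert/substitute with
// a 0/1 mismatch indicator. Two rolling rows keep memory at O(|s2|).
static int edit_distance(const std::string &s1, const std::string &s2) {
  const size_t n1 = s1.size(), n2 = s2.size();
  if (n1 == 0) return (int)n2;
  if (n2 == 0) return (int)n1;
  std::vector<int> prev(n2 + 1), cur(n2 + 1);
  for (size_t q = 0; q <= n2; ++q) prev[q] = (int)q;
  for (size_t p = 1; p <= n1; ++p) {
    cur[0] = (int)p;
    const char c1 = s1[p - 1];
    for (size_t q = 1; q <= n2; ++q) {
      const int sub = prev[q - 1] + (c1 == s2[q - 1] ? 0 : 1);
      const int del = prev[q] + 1;
      const int ins = cur[q - 1] + 1;
      int best = sub < del ? sub : del;
      if (ins < best) best = ins;
      cur[q] = best;
    }
    prev.swap(cur);
  }
  return prev[n2];
}

// [[Rcpp::export]]
int levenshtein_cpp(std::string s1, std::string s2) {
  return edit_distance(s1, s2);
}

// All-pairs normalised sequence similarity 1 - LD/max(len); diagonal 1.
// [[Rcpp::export]]
Rcpp::NumericMatrix seq_similarity_cpp(Rcpp::CharacterVector seqs) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = Rcpp::as<std::string>(seqs[i]);
  Rcpp::NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      const double mx = (double)std::max(s[i].size(), s[j].size());
      double sim = 1.0;
      if (mx > 0) sim = 1.0 - (double)edit_distance(s[i], s[j]) / mx;
      out(i, j) = sim;
      out(j, i) = sim;
    }
  }
  return out;
}
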