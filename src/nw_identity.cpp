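#include <Rcpp.h>
#include <string>
#include <vector>

// Global (Needleman-Wunsch style) alignment with unit match score and
// zero mismatch/gap scores, i.e. the alignment maximizing the number of
// matched columns.  Percent identity = matches / alignment columns * 100.
// Traceback prefers diagonal moves on ties (then up, then left) so the
// reported alignment length is deterministic.  'N' never matches.

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T' || c == 'N';
}

// [[Rcpp::export]]
double nw_percent_identity(const std::string& a_in, const std::string& b_in) {
  // canonical operand order makes the tie-broken alignment length (and
  // hence the score) exactly symmetric in its arguments
  const bool swap = b_in < a_in;
  const std::string& a = swap ? b_in : a_in;
  const std::string& b = swap ? a_in : b_in;
  const int la = a.size(), lb = b.size();
  if (la == 0 || lb == 0)
    Rcpp::stop("sequences must be non-empty");
  for (int i = 0; i < la; ++i)
    if (!valid_base(a[i]))
      Rcpp::stop("invalid character '%c' in sequence (ACGTN only)", a[i]);
  for (int j = 0; j < lb; ++j)
    if (!valid_base(b[j]))
      Rcpp::stop("invalid character '%c' in sequence (ACGTN only)", b[j]);

  std::vector<int> S((la + 1) * (lb + 1), 0);
  const int W = lb + 1;
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      const int m = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? 1 : 0;
      int best = S[(i - 1) * W + (j - 1)] + m;
      const int up = S[(i - 1) * W + j];
      const int left = S[i * W + (j - 1)];
      if (up > best) best = up;
      if (left > best) best = left;
      S[i * W + j] = best;
    }
  }

  int i = la, j = lb, matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      const int m = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? 1 : 0;
      if (S[i * W + j] == S[(i - 1) * W + (j - 1)] + m) {
        matches += m; ++cols; --i; --j; continue;
      }
    }
    if (i > 0 && S[i * W + j] == S[(i - 1) * W + j]) { ++cols; --i; continue; }
    ++cols; --j;
  }
  return 100.0 * matches / cols;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix nw_identity_matrix(const std::vector<std::string>& seqs) {
  const int n = seqs.size();
  Rcpp::NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 100.0;
    for (int j = i + 1; j < n; ++j) {
      const double v = nw_percent_identity(seqs[i], seqs[j]);
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}
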