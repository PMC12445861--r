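#include <Rcpp.h>
#include <string>
#include <vector>

// Global (end-to-end) alignment maximizing the number of matched
// positions, with mismatches and gaps contributing 0 to the score but 1
// column each to the alignment length. Among alignments with the maximal
// match count, the one with the fewest columns is taken, so a single
// substitution is preferred over a gap pair. Identity is then
// matches / alignment length, the convention used for the 97 % OTU
// threshold.
//
// DP state per cell: best match count M[i][j] and, among alignments
// achieving it, minimal alignment length L[i][j].

// [[Rcpp::export]]
Rcpp::List aligned_identity_cpp(std::string a, std::string b) {
  const int n = static_cast<int>(a.size());
  const int m = static_cast<int>(b.size());
  if (n == 0 || m == 0)
    Rcpp::stop("Sequences must be non-empty.");

  std::vector<int> prevM(m + 1), prevL(m + 1), curM(m + 1), curL(m + 1);
  for (int j = 0; j <= m; ++j) {
    prevM[j] = 0;
    prevL[j] = j; // leading gaps in a
  }
  for (int i = 1; i <= n; ++i) {
    curM[0] = 0;
    curL[0] = i; // leading gaps in b
    for (int j = 1; j <= m; ++j) {
      int bestM = prevM[j - 1] + (a[i - 1] == b[j - 1] ? 1 : 0);
      int bestL = prevL[j - 1] + 1;
      // gap in b (consume a[i-1])
      if (prevM[j] > bestM || (prevM[j] == bestM && prevL[j] + 1 < bestL)) {
        bestM = prevM[j];
        bestL = prevL[j] + 1;
      }
      // gap in a (consume b[j-1])
      if (curM[j - 1] > bestM ||
          (curM[j - 1] == bestM && curL[j - 1] + 1 < bestL)) {
        bestM = curM[j - 1];
        bestL = curL[j - 1] + 1;
      }
      curM[j] = bestM;
      curL[j] = bestL;
    }
    std::swap(prevM, curM);
    std::swap(prevL, curL);
  }
  const int matches = prevM[m];
  const int len = prevL[m];
  return Rcpp::List::create(
      Rcpp::Named("matches") = matches, Rcpp::Named("length") = len,
      Rcpp::Named("identity") = static_cast<double>(matches) / len);
}
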