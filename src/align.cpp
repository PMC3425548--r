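#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with match +1, mismatch 0, linear gap
// penalty -1. Among maximal-score alignments the one with the fewest gap
// columns is taken (score and gap count together determine the number of
// matched columns and the alignment length, so no traceback is required):
//   score = matches - gaps,  columns = (m + n + gaps) / 2.
// Identity is matches / columns, i.e. normalised by alignment length
// including gap columns.

// [[Rcpp::export(name = ".nw_identity_cpp")]]
List nw_identity_cpp(std::string a, std::string b) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0)
    stop("empty sequence");
  const int NEG = -1000000000;
  std::vector<int> S_prev(n + 1), S_cur(n + 1);  // best score
  std::vector<int> G_prev(n + 1), G_cur(n + 1);  // min gaps among best-score
  for (int j = 0; j <= n; ++j) { S_prev[j] = -j; G_prev[j] = j; }
  for (int i = 1; i <= m; ++i) {
    S_cur[0] = -i; G_cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      int sd = S_prev[j - 1] + (a[i - 1] == b[j - 1] ? 1 : 0);
      int gd = G_prev[j - 1];
      int su = S_prev[j] - 1, gu = G_prev[j] + 1;
      int sl = S_cur[j - 1] - 1, gl = G_cur[j - 1] + 1;
      int s = NEG, g = 0;
      // lexicographic: maximise score, then minimise gaps
      if (sd > s || (sd == s && gd < g)) { s = sd; g = gd; }
      if (su > s || (su == s && gu < g)) { s = su; g = gu; }
      if (sl > s || (sl == s && gl < g)) { s = sl; g = gl; }
      S_cur[j] = s; G_cur[j] = g;
    }
    std::swap(S_prev, S_cur);
    std::swap(G_prev, G_cur);
  }
  int score = S_prev[n], gaps = G_prev[n];
  int matches = score + gaps;
  int columns = (m + n + gaps) / 2;
  return List::create(_["score"] = score, _["gaps"] = gaps,
                      _["matches"] = matches, _["columns"] = columns,
                      _["identity"] = (double)matches / (double)columns);
}
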