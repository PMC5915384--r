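#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global Levenshtein alignment of a read against a bisulfite-converted
// amplicon template in which designated positions (CpG cytosines) are
// wildcards matching either C or T, so that a molecule's methylation state
// cannot alter its similarity to the target. Unit costs for mismatch,
// insertion and deletion. 'N' in the read matches nothing.
//
// Returns the edit distance and, from the traceback, the 1-based read index
// aligned to each template position (NA where the template position is
// deleted in the read). Ties in the traceback prefer diagonal moves, then
// deletion, so the mapping is deterministic.

static inline bool base_match(char r, char t, bool wild) {
  if (wild) return r == 'C' || r == 'T';
  return r == t && r != 'N';
}

// [[Rcpp::export(name = ".wildcard_align_cpp")]]
List wildcard_align_cpp(std::string read, std::string tmpl,
                        IntegerVector wildcard_pos) {
  const int n = read.size();   // rows: read
  const int m = tmpl.size();   // cols: template
  std::vector<bool> wild(m + 1, false);
  for (int k = 0; k < wildcard_pos.size(); ++k) {
    int p = wildcard_pos[k];
    if (p >= 1 && p <= m) wild[p] = true;
  }

  // full DP matrix (templates are short amplicons, so (n+1)*(m+1) is small)
  std::vector<int> dp((n + 1) * (m + 1));
  const int W = m + 1;
  for (int j = 0; j <= m; ++j) dp[j] = j;
  for (int i = 1; i <= n; ++i) {
    dp[i * W] = i;
    const char rc = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      int sub = dp[(i - 1) * W + (j - 1)] +
                (base_match(rc, tmpl[j - 1], wild[j]) ? 0 : 1);
      int del = dp[i * W + (j - 1)] + 1;       // template pos j unmatched
      int ins = dp[(i - 1) * W + j] + 1;       // extra read base
      int best = sub;
      if (del < best) best = del;
      if (ins < best) best = ins;
      dp[i * W + j] = best;
    }
  }

  // traceback: template position -> read index
  IntegerVector tpos_to_read(m, NA_INTEGER);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int cur = dp[i * W + j];
    if (i > 0 && j > 0 &&
        cur == dp[(i - 1) * W + (j - 1)] +
                 (base_match(read[i - 1], tmpl[j - 1], wild[j]) ? 0 : 1)) {
      tpos_to_read[j - 1] = i;
      --i; --j;
    } else if (j > 0 && cur == dp[i * W + (j - 1)] + 1) {
      --j;  // deletion: template position left unmapped
    } else {
      --i;  // insertion in read
    }
  }

  return List::create(_["dist"] = dp[n * W + m],
                      _["tpos_to_read"] = tpos_to_read);
}
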