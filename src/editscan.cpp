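#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Semi-global (free genome start/end) edit-distance scan of `pattern`
// against `text`. Returns every 1-based end position in `text` at which
// some alignment of the full pattern ends with Levenshtein distance
// <= max_edits. A pattern character 'N' matches any text character at
// zero cost (the PAM wildcard).
// [[Rcpp::export(name = ".edit_end_positions")]]
IntegerVector edit_end_positions(std::string text, std::string pattern,
                                 int max_edits) {
  const int m = (int)pattern.size();
  const int n = (int)text.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<int> out;
  for (int i = 0; i <= m; ++i) prev[i] = i;  // empty text: delete prefix
  for (int j = 1; j <= n; ++j) {
    cur[0] = 0;  // free start anywhere in the genome
    const char tc = text[j - 1];
    for (int i = 1; i <= m; ++i) {
      const char pc = pattern[i - 1];
      int v = prev[i - 1] + ((pc == 'N' || pc == tc) ? 0 : 1);
      const int del = prev[i] + 1;
      if (del < v) v = del;
      const int ins = cur[i - 1] + 1;
      if (ins < v) v = ins;
      cur[i] = v;
    }
    if (cur[m] <= max_edits) out.push_back(j);
    std::swap(prev, cur);
  }
  return wrap(out);
}
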