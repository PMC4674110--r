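#include <Rcpp.h>
using namespace Rcpp;

// Markov walk over the song grammar for one bird's renditions.
//
// Labels are integer-coded 1..L; 0 is the reserved end token. Transition
// rules are stored flat: rule r covers targets rule_tgt[rule_off[r-1] ..
// rule_off[r]-1] with cumulative probabilities rule_cum over the same range.
// lookup2(prev, cur) resolves a history-dependent (order-2) context, falling
// back to lookup1[cur]; a zero lookup means the walk terminates (dead end).
// Draws use R's RNG so a fixed seed reproduces the corpus exactly.
//
// Returns flat label and generating-rule vectors plus per-rendition lengths.
// [[Rcpp::export(name = ".cpp_walk")]]
List cpp_walk(int n_rend, int max_syl, int start,
              IntegerVector lookup1, IntegerMatrix lookup2,
              IntegerVector rule_off, IntegerVector rule_tgt,
              NumericVector rule_cum) {
  std::vector<int> labels, ctxrule;
  labels.reserve(n_rend * 32);
  ctxrule.reserve(n_rend * 32);
  IntegerVector lengths(n_rend);
  int L = lookup1.size();

  for (int r = 0; r < n_rend; ++r) {
    int cur = start, prev = 0, len = 1;
    labels.push_back(cur);
    ctxrule.push_back(0);
    while (len < max_syl) {
      int rule = 0;
      if (prev > 0) rule = lookup2(prev - 1, cur - 1);
      if (rule == 0) rule = lookup1[cur - 1];
      if (rule == 0) break;                    // dead end: termination
      int lo = rule_off[rule - 1], hi = rule_off[rule];
      double u = unif_rand();
      int k = lo;
      while (k < hi - 1 && u > rule_cum[k]) ++k;
      int nxt = rule_tgt[k];
      if (nxt == 0) break;                     // end token: termination
      labels.push_back(nxt);
      ctxrule.push_back(rule);
      prev = cur;
      cur = nxt;
      ++len;
    }
    lengths[r] = len;
    (void)L;
  }
  return List::create(_["labels"] = wrap(labels),
                      _["ctxrule"] = wrap(ctxrule),
                      _["lengths"] = lengths);
}
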