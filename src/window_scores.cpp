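#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Windowed sums of per-position integer scores over an integer-coded
// sequence: out[i] = sum_l K(l, codes[i+l-1]); windows touching an NA code
// (non-ACGT base) yield NA. Codes are 1..4 for A,C,G,T.
// [[Rcpp::export(name = ".window_scores_int")]]
IntegerVector window_scores_int(IntegerVector codes, IntegerMatrix K) {
  const int n = codes.size();
  const int L = K.nrow();
  const int nw = n - L + 1;
  if (nw < 1) return IntegerVector(0);
  std::vector<int> k((size_t) L * 4);
  for (int l = 0; l < L; ++l)
    for (int b = 0; b < 4; ++b) k[(size_t) l * 4 + b] = K(l, b);
  const int *cp = INTEGER(codes);
  IntegerVector out(nw);
  int *op = INTEGER(out);
  for (int i = 0; i < nw; ++i) {
    const int *w = cp + i;
    long s = 0;
    bool ok = true;
    for (int l = 0; l < L; ++l) {
      const int c = w[l];
      if (c == NA_INTEGER) { ok = false; break; }
      s += k[(size_t) l * 4 + (c - 1)];
    }
    op[i] = ok ? (int) s : NA_INTEGER;
  }
  return out;
}
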