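#include <Rcpp.h>
using namespace Rcpp;

// Leftmost position where a prefix of `adapter` matches the read suffix with at
// most max_mm_rate mismatches over the overlap (overlap >= min_overlap, or the
// full adapter if it fits entirely).  Returns the 0-based position where the
// adapter starts, i.e. the retained insert length; the read length if no match.
// [[Rcpp::export]]
IntegerVector cpp_adapter_pos(CharacterVector reads, std::string adapter,
                              int min_overlap, double max_mm_rate) {
  int n = reads.size();
  int alen = adapter.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    const char *seq = CHAR(STRING_ELT(reads, r));
    int len = LENGTH(STRING_ELT(reads, r));
    int pos = len;
    for (int p = 0; p + min_overlap <= len; ++p) {
      int ov = std::min(len - p, alen);
      int max_mm = (int)std::floor(max_mm_rate * ov);
      int mm = 0;
      bool ok = true;
      for (int i = 0; i < ov; ++i) {
        if (seq[p + i] != adapter[i]) {
          if (++mm > max_mm) { ok = false; break; }
        }
      }
      if (ok) { pos = p; break; }
    }
    out[r] = pos;
  }
  return out;
}
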