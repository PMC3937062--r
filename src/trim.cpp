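#include <Rcpp.h>
#include <string>

// Left-most adapter-prefix scan used by trim_adapter(); N matches nothing.
// Returns, per read, the 0-based position where the adapter starts, or -1
// when no admissible match exists.
// [[Rcpp::export(name = ".adapter_scan")]]
Rcpp::IntegerVector adapter_scan(Rcpp::CharacterVector reads,
                                 std::string adapter,
                                 int min_seed, int max_mismatch) {
  int nr = reads.size();
  int la = adapter.size();
  Rcpp::IntegerVector out(nr, -1);
  for (int r = 0; r < nr; ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int n = LENGTH(STRING_ELT(reads, r));
    for (int p = 0; p < n; ++p) {
      int ov = std::min(la, n - p);
      if (ov < min_seed) break;
      int mm = 0;
      for (int i = 0; i < ov && mm <= max_mismatch; ++i) {
        char a = s[p + i], b = adapter[i];
        if (a != b || a == 'N' || b == 'N') ++mm;
      }
      if (mm <= max_mismatch) { out[r] = p; break; }
    }
  }
  return out;
}
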