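#include <Rcpp.h>
using namespace Rcpp;

// Leftmost seed-and-extend match of a 3' adapter in each read.
// Seed = first seed_len adapter bases, at most seed_mm mismatches in the
// seed; extension compares the full adapter prefix over the read suffix and
// accepts at most max_mm total mismatches. Returns the 1-based position of
// the first adapter base, or NA when no acceptable match exists.
// [[Rcpp::export]]
IntegerVector trim_adapter_cpp(CharacterVector reads, std::string adapter,
                               int seed_len, int seed_mm, int max_mm) {
  int n = reads.size();
  int alen = (int) adapter.size();
  if (seed_len > alen) seed_len = alen;
  IntegerVector out(n, NA_INTEGER);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(reads[r]);
    int L = (int) s.size();
    for (int p = 0; p + seed_len <= L; ++p) {
      int mm = 0;
      for (int i = 0; i < seed_len && mm <= seed_mm; ++i)
        if (s[p + i] != adapter[i]) ++mm;
      if (mm > seed_mm) continue;
      // extend over the full adapter prefix that fits in the read
      int ov = std::min(alen, L - p);
      int tot = 0;
      for (int i = 0; i < ov && tot <= max_mm; ++i)
        if (s[p + i] != adapter[i]) ++tot;
      if (tot <= max_mm) { out[r] = p + 1; break; }
    }
  }
  return out;
}
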