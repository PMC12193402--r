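#include <Rcpp.h>
using namespace Rcpp;

// Per-record CIGAR accounting: query length, aligned (non-clipped) query
// length, reference span. "*" yields zeros.

// [[Rcpp::export]]
IntegerMatrix cigar_stats_cpp(CharacterVector cigar) {
  int n = cigar.size();
  IntegerMatrix out(n, 3);
  colnames(out) = CharacterVector::create("qlen", "aligned_qlen",
                                          "ref_span");
  for (int r = 0; r < n; ++r) {
    std::string cg = as<std::string>(cigar[r]);
    if (cg == "*") continue;
    long qlen = 0, alen = 0, rspan = 0, len = 0;
    for (size_t i = 0; i < cg.size(); ++i) {
      char c = cg[i];
      if (isdigit(c)) { len = len * 10 + (c - '0'); continue; }
      switch (c) {
        case 'M': case '=': case 'X':
          qlen += len; alen += len; rspan += len; break;
        case 'I': qlen += len; alen += len; break;
        case 'S': qlen += len; break;
        case 'D': case 'N': rspan += len; break;
        default: break; // H, P
      }
      len = 0;
    }
    out(r, 0) = (int) qlen; out(r, 1) = (int) alen; out(r, 2) = (int) rspan;
  }
  out;
  return out;
}
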