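#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Banded affine-gap alignment, global in the query and local in the
// reference window (free leading/trailing reference gaps).  The band is
// centred on the diagonal implied by `offset`, the expected 1-based start
// of the query within the window (amplicon reads start at primer starts,
// so the diagonal is known up to the indel length).
//
// Gap of length L costs gap_open + L * gap_ext (both negative).
// Tie-breaking in traceback: diagonal, then deletion (ref gap), then
// insertion; interior indels are canonicalised later by left-normalization.

static const double NEG_INF = -1e18;

// [[Rcpp::export]]
List align_banded_cpp(std::string query, std::string ref, int offset,
                      int band, double match, double mismatch,
                      double gap_open, double gap_ext) {
  const int m = (int) query.size();
  const int n = (int) ref.size();
  if (m < 1) stop("empty query");
  if (n < 1) stop("empty reference window");
  const int W = 2 * band + 1;

  std::vector<double> Hprev(W, NEG_INF), Hcur(W, NEG_INF);
  std::vector<double> Fprev(W, NEG_INF), Fcur(W, NEG_INF);
  std::vector<double> Ecur(W, NEG_INF);
  // traceback: 2 bits H-source (0 diag, 1 E, 2 F, 3 none/start),
  // bit2: E extends E, bit3: F extends F
  std::vector<unsigned char> tb((size_t)(m + 1) * W, 3);

  // row 0: free leading reference gap
  {
    int jc = offset - 1;
    for (int k = 0; k < W; ++k) {
      int j = jc - band + k;
      if (j >= 0 && j <= n) Hprev[k] = 0.0;
    }
  }

  for (int i = 1; i <= m; ++i) {
    int jc = offset - 1 + i;
    std::fill(Hcur.begin(), Hcur.end(), NEG_INF);
    std::fill(Ecur.begin(), Ecur.end(), NEG_INF);
    std::fill(Fcur.begin(), Fcur.end(), NEG_INF);
    char qc = query[i - 1];
    for (int k = 0; k < W; ++k) {
      int j = jc - band + k;
      if (j < 1 || j > n) continue;
      unsigned char t = 0;
      // E: gap in query (deletion of ref base j), from (i, j-1) = k-1
      double e = NEG_INF;
      bool e_ext = false;
      if (k - 1 >= 0) {
        double open_e = Hcur[k - 1] + gap_open + gap_ext;
        double ext_e  = Ecur[k - 1] + gap_ext;
        if (ext_e > open_e) { e = ext_e; e_ext = true; } else e = open_e;
      }
      // F: gap in ref (insertion of query base i), from (i-1, j) = prev k+1
      double f = NEG_INF;
      bool f_ext = false;
      if (k + 1 < W) {
        double open_f = Hprev[k + 1] + gap_open + gap_ext;
        double ext_f  = Fprev[k + 1] + gap_ext;
        if (ext_f > open_f) { f = ext_f; f_ext = true; } else f = open_f;
      }
      // diagonal from (i-1, j-1) = prev k
      double d = Hprev[k];
      if (d > NEG_INF / 2) d += (qc == ref[j - 1] ? match : mismatch);
      double best = d;
      unsigned char src = 0;
      if (e > best) { best = e; src = 1; }
      if (f > best) { best = f; src = 2; }
      if (best <= NEG_INF / 2) src = 3;
      Hcur[k] = best;
      Ecur[k] = e;
      Fcur[k] = f;
      t = src;
      if (e_ext) t |= 4;
      if (f_ext) t |= 8;
      tb[(size_t)i * W + k] = t;
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
    // Ecur only needed within its own row
  }

  // best end in last row (free trailing reference gap)
  int jc_m = offset - 1 + m;
  double best = NEG_INF;
  int kend = -1;
  for (int k = 0; k < W; ++k) {
    int j = jc_m - band + k;
    if (j < 0 || j > n) continue;
    if (Hprev[k] > best) { best = Hprev[k]; kend = k; }
  }
  if (kend < 0 || best <= NEG_INF / 2)
    stop("no alignment within band; widen band or check offset");

  // traceback
  std::string ops;
  int i = m;
  int j = jc_m - band + kend;
  int state = 0; // 0 = in H, 1 = in E, 2 = in F
  while (i > 0) {
    int jc = offset - 1 + i;
    int k = j - (jc - band);
    unsigned char t = tb[(size_t)i * W + k];
    if (state == 0) {
      int src = t & 3;
      if (src == 0) { ops.push_back('M'); --i; --j; }
      else if (src == 1) state = 1;
      else if (src == 2) state = 2;
      else stop("traceback hit invalid cell");
    } else if (state == 1) {
      ops.push_back('D');
      bool ext = (t & 4) != 0;
      --j;
      if (!ext) state = 0;
    } else {
      ops.push_back('I');
      bool ext = (t & 8) != 0;
      --i;
      if (!ext) state = 0;
    }
  }
  int pos = j + 1; // 1-based start within window

  // run-length encode reversed ops
  std::string cigar;
  int run = 0;
  char cur = 0;
  for (int x = (int) ops.size() - 1; x >= 0; --x) {
    char c = ops[x];
    if (c == cur) ++run;
    else {
      if (run > 0) cigar += std::to_string(run) + cur;
      cur = c; run = 1;
    }
  }
  if (run > 0) cigar += std::to_string(run) + cur;

  return List::create(_["score"] = best, _["pos"] = pos, _["cigar"] = cigar);
}
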