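#include <Rcpp.h>
#include <map>
#include <string>
#include <utility>
using namespace Rcpp;

// Pileup accumulation over a reference window.
//
// Physical spanning depth (`cov`) counts every read base aligned (M) or
// deleted (D) at a position, with no quality gate: depth is physical
// coverage, so nested deletion alleles share a common denominator.
// Per-base substitution support is gated at min_q (Phred); deletions and
// insertions carry no per-base quality at the event itself, so they are
// exempt and record the mean quality of the flanking / inserted read bases.
// A deletion allele "-SEQ" (SEQ = deleted reference bases) is registered
// once per read at its anchor, the aligned base immediately 5' of the gap;
// an insertion "+SEQ" likewise at the base it follows.

struct IndelRec { int count = 0; double qualsum = 0.0; int rev = 0; };

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
List pileup_cpp(int wstart, std::string ref,
                IntegerVector pos, CharacterVector cigar,
                CharacterVector seq, CharacterVector qual,
                LogicalVector rev, int min_q) {
  const int wlen = (int) ref.size();
  const int nreads = pos.size();
  IntegerVector cov(wlen);
  IntegerMatrix bc(4, wlen);      // substitution-support counts (q >= min_q)
  NumericMatrix bq(4, wlen);      // summed Phred of those bases
  IntegerMatrix brv(4, wlen);     // reverse-strand subset
  std::map<std::pair<int, std::string>, IndelRec> indels;

  for (int r = 0; r < nreads; ++r) {
    std::string cg = as<std::string>(cigar[r]);
    std::string sq = as<std::string>(seq[r]);
    std::string ql = as<std::string>(qual[r]);
    bool is_rev = rev[r];
    long rpos = pos[r];   // 1-based genome
    size_t qpos = 0;      // 0-based in read
    size_t ci = 0;
    while (ci < cg.size()) {
      long len = 0;
      while (ci < cg.size() && isdigit(cg[ci])) { len = len * 10 + (cg[ci] - '0'); ++ci; }
      if (ci >= cg.size()) stop("malformed CIGAR: %s", cg);
      char op = cg[ci++];
      if (op == 'M' || op == '=' || op == 'X') {
        for (long t = 0; t < len; ++t) {
          long w = rpos + t - wstart;
          if (w >= 0 && w < wlen) {
            cov[w]++;
            int q = (int) ql[qpos + t] - 33;
            if (q >= min_q) {
              int b = base_idx(sq[qpos + t]);
              if (b >= 0) {
                bc(b, w)++;
                bq(b, w) += q;
                if (is_rev) brv(b, w)++;
              }
            }
          }
        }
        rpos += len; qpos += len;
      } else if (op == 'D') {
        long w0 = rpos - wstart;
        for (long t = 0; t < len; ++t) {
          long w = w0 + t;
          if (w >= 0 && w < wlen) cov[w]++;
        }
        long anchor = rpos - 1;
        if (anchor >= wstart && w0 + len <= wlen && w0 >= 0) {
          std::string del = ref.substr(w0, len);
          double fq;
          if (qpos > 0 && qpos < sq.size())
            fq = 0.5 * ((ql[qpos - 1] - 33) + (ql[qpos] - 33));
          else if (qpos > 0) fq = ql[qpos - 1] - 33;
          else fq = ql[qpos] - 33;
          IndelRec &ir = indels[{(int) anchor, "-" + del}];
          ir.count++; ir.qualsum += fq; if (is_rev) ir.rev++;
        }
        rpos += len;
      } else if (op == 'I') {
        long anchor = rpos - 1;
        if (anchor >= wstart && anchor - wstart < wlen) {
          std::string ins = sq.substr(qpos, len);
          double qs = 0.0;
          for (long t = 0; t < len; ++t) qs += ql[qpos + t] - 33;
          IndelRec &ir = indels[{(int) anchor, "+" + ins}];
          ir.count++; ir.qualsum += qs / len; if (is_rev) ir.rev++;
        }
        qpos += len;
      } else if (op == 'S') {
        qpos += len;
      } else if (op == 'H' || op == 'N' || op == 'P') {
        if (op == 'N') rpos += len;
      } else {
        stop("unsupported CIGAR op '%c'", op);
      }
    }
    if (qpos != sq.size())
      stop("CIGAR inconsistent with read length for read %d", r + 1);
  }

  int ni = (int) indels.size();
  IntegerVector ipos(ni), icount(ni), irev(ni);
  CharacterVector iall(ni);
  NumericVector iqual(ni);
  int k = 0;
  for (auto &kv : indels) {
    ipos[k] = kv.first.first;
    iall[k] = kv.first.second;
    icount[k] = kv.second.count;
    iqual[k] = kv.second.count > 0 ? kv.second.qualsum / kv.second.count : 0.0;
    irev[k] = kv.second.rev;
    ++k;
  }
  return List::create(
    _["cov"] = cov, _["base_count"] = bc, _["base_qualsum"] = bq,
    _["base_rev"] = brv,
    _["indel"] = DataFrame::create(
      _["pos"] = ipos, _["allele"] = iall, _["count"] = icount,
      _["mean_qual"] = iqual, _["rev"] = irev,
      _["stringsAsFactors"] = false));
}
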