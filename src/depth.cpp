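#include <Rcpp.h>
#include <cctype>
#include "dna.h"

using namespace Rcpp;

/* Per-base depth accumulation.  CIGAR M/=/X consume reference and add depth,
   D/N consume reference only, I/S/H/P consume none.  Records below mapq_min
   or unmapped (rname_idx NA) contribute nothing. */
// [[Rcpp::export]]
List cpp_depth(IntegerVector contig_len, IntegerVector rname_idx,
               IntegerVector pos, CharacterVector cigar, IntegerVector mapq,
               int mapq_min) {
  int nc = contig_len.size();
  List out(nc);
  std::vector<int *> ptrs(nc);
  for (int i = 0; i < nc; ++i) {
    IntegerVector v(contig_len[i]); // zero-initialized
    out[i] = v;
    ptrs[i] = INTEGER(v);
  }
  R_xlen_t n = rname_idx.size();
  for (R_xlen_t r = 0; r < n; ++r) {
    if (rname_idx[r] == NA_INTEGER || mapq[r] < mapq_min) continue;
    int ci = rname_idx[r] - 1;
    if (ci < 0 || ci >= nc) stop("alignment %d references unknown contig", (int)(r + 1));
    int64_t ref = pos[r] - 1; /* 0-based */
    const char *c = CHAR(STRING_ELT(cigar, r));
    int64_t len = 0;
    for (; *c; ++c) {
      if (isdigit((unsigned char)*c)) {
        len = len * 10 + (*c - '0');
        continue;
      }
      switch (*c) {
      case 'M': case '=': case 'X':
        if (ref < 0 || ref + len > contig_len[ci])
          stop("alignment %d extends past contig end", (int)(r + 1));
        for (int64_t j = 0; j < len; ++j) ++ptrs[ci][ref + j];
        ref += len;
        break;
      case 'D': case 'N':
        ref += len;
        break;
      case 'I': case 'S': case 'H': case 'P':
        break;
      default:
        stop("alignment %d has unsupported CIGAR op '%c'", (int)(r + 1), *c);
      }
      len = 0;
    }
  }
  return out;
}
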