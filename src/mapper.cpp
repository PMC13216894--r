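#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include "dna.h"

using namespace Rcpp;

/* Seed index: canonical w-mer -> packed forward positions ((contig<<40)|pos0).
   Querying both read orientations with forward extension recovers both-strand
   placements; a canonical hit in the wrong orientation simply fails extension. */
struct SeedIndex {
  int w;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<uint64_t>> table;
};

static void index_contig(SeedIndex &idx, size_t ci) {
  const std::string &s = idx.seqs[ci];
  const int w = idx.w;
  const uint64_t mask = kmer_mask(w);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  const int shift = 2 * (w - 1);
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= w) {
      uint64_t pos0 = i + 1 - w;
      idx.table[fwd < rev ? fwd : rev].push_back(((uint64_t)ci << 40) | pos0);
    }
  }
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int w) {
  if (w < 2 || w > 31) stop("seed length w must be between 2 and 31");
  if (seqs.size() == 0) stop("empty genome: nothing to index");
  XPtr<SeedIndex> p(new SeedIndex(), true);
  p->w = w;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    p->names.push_back(as<std::string>(names[i]));
    p->seqs.push_back(as<std::string>(seqs[i]));
    if (p->seqs.back().empty()) stop("contig '%s' has empty sequence",
                                     p->names.back().c_str());
    index_contig(*p, (size_t)i);
  }
  return p;
}

// [[Rcpp::export]]
int cpp_index_w(SEXP idx) { return XPtr<SeedIndex>(idx)->w; }

// [[Rcpp::export]]
CharacterVector cpp_index_contigs(SEXP idx) {
  XPtr<SeedIndex> p(idx);
  return wrap(p->names);
}

// [[Rcpp::export]]
IntegerVector cpp_index_contig_lengths(SEXP idx) {
  XPtr<SeedIndex> p(idx);
  IntegerVector out(p->seqs.size());
  for (size_t i = 0; i < p->seqs.size(); ++i) out[i] = (int)p->seqs[i].size();
  return out;
}

/* All stored positions of a w-mer (queried canonically): contig index and
   1-based forward position. */
// [[Rcpp::export]]
DataFrame cpp_index_lookup(SEXP idx, std::string wmer) {
  XPtr<SeedIndex> p(idx);
  if ((int)wmer.size() != p->w) stop("query length must equal seed length w");
  uint64_t code = 0;
  for (char c : wmer) {
    int b = base2bits(c);
    if (b < 0)
      return DataFrame::create(_["contig"] = IntegerVector(0),
                               _["pos"] = IntegerVector(0));
    code = (code << 2) | (uint64_t)b;
  }
  auto it = p->table.find(canonical_code(code, p->w));
  std::vector<int> contig, pos;
  if (it != p->table.end()) {
    for (uint64_t packed : it->second) {
      contig.push_back((int)(packed >> 40) + 1);
      pos.push_back((int)(packed & ((1ULL << 40) - 1)) + 1);
    }
  }
  return DataFrame::create(_["contig"] = wrap(contig), _["pos"] = wrap(pos));
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (char &c : r) {
    switch (c) {
    case 'A': c = 'T'; break; case 'C': c = 'G'; break;
    case 'G': c = 'C'; break; case 'T': c = 'A'; break;
    case 'a': c = 't'; break; case 'c': c = 'g'; break;
    case 'g': c = 'c'; break; case 't': c = 'a'; break;
    default: c = 'N';
    }
  }
  return r;
}

/* Ungapped extension; returns mismatch count or max_mm+1 on early abort.
   Any non-ACGT pair (e.g. reference N) counts as a mismatch. */
static int extend_count(const std::string &ref, size_t start,
                        const std::string &read, int max_mm) {
  int mm = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    char a = read[i], b = ref[start + i];
    int ba = base2bits(a), bb = base2bits(b);
    if (ba < 0 || bb < 0 || ba != bb) {
      if (++mm > max_mm) return max_mm + 1;
    }
  }
  return mm;
}

/* Map reads: every read offset is seeded in both orientations; every seeded
   placement fully inside a contig is extended ungapped.  Best = fewest
   mismatches, ties broken by (contig, position, strand); MAPQ 60/20/0 by the
   margin over the runner-up among acceptable placements. */
// [[Rcpp::export]]
DataFrame cpp_map_reads(SEXP idx, CharacterVector seqs, int max_mm) {
  XPtr<SeedIndex> p(idx);
  const int w = p->w;
  const uint64_t mask = kmer_mask(w);
  const int shift = 2 * (w - 1);
  R_xlen_t n = seqs.size();
  LogicalVector mapped(n);
  IntegerVector contig(n), pos(n), mm_out(n), mapq(n);
  LogicalVector rev_strand(n);
  std::unordered_set<uint64_t> seen;

  for (R_xlen_t r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(seqs[r]);
    if ((int)fwd.size() < w) stop("read %d is shorter than seed length", (int)(r + 1));
    std::string rev = revcomp_str(fwd);
    const size_t rl = fwd.size();
    seen.clear();
    int best_mm = max_mm + 1, second_mm = max_mm + 1;
    uint64_t best_key = ~0ULL;
    int best_ci = -1, best_pos = -1, best_ori = 0;

    for (int ori = 0; ori < 2; ++ori) {
      const std::string &s = ori ? rev : fwd;
      uint64_t fc = 0, rc = 0;
      int run = 0;
      for (size_t i = 0; i < rl; ++i) {
        int b = base2bits(s[i]);
        if (b < 0) { run = 0; fc = 0; rc = 0; continue; }
        fc = ((fc << 2) | (uint64_t)b) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
        if (++run < w) continue;
        auto it = p->table.find(fc < rc ? fc : rc);
        if (it == p->table.end()) continue;
        size_t off = i + 1 - w;
        for (uint64_t packed : it->second) {
          int ci = (int)(packed >> 40);
          int64_t start = (int64_t)(packed & ((1ULL << 40) - 1)) - (int64_t)off;
          if (start < 0 || (size_t)start + rl > p->seqs[ci].size()) continue;
          uint64_t key = ((uint64_t)ori << 62) | ((uint64_t)ci << 40) |
                         (uint64_t)start;
          if (!seen.insert(key).second) continue;
          int mm = extend_count(p->seqs[ci], (size_t)start, s, max_mm);
          if (mm > max_mm) continue;
          /* ordering key for tie-break: (contig, position, strand) */
          uint64_t ord = ((uint64_t)ci << 41) | ((uint64_t)start << 1) |
                         (uint64_t)ori;
          if (mm < best_mm) {
            second_mm = best_mm;
            best_mm = mm; best_key = ord;
            best_ci = ci; best_pos = (int)start; best_ori = ori;
          } else if (mm == best_mm) {
            second_mm = mm;
            if (ord < best_key) {
              best_key = ord; best_ci = ci; best_pos = (int)start;
              best_ori = ori;
            }
          } else if (mm < second_mm) {
            second_mm = mm;
          }
        }
      }
    }

    if (best_mm > max_mm) {
      mapped[r] = false;
      contig[r] = NA_INTEGER; pos[r] = NA_INTEGER;
      mm_out[r] = NA_INTEGER; mapq[r] = 0; rev_strand[r] = false;
    } else {
      mapped[r] = true;
      contig[r] = best_ci + 1;
      pos[r] = best_pos + 1;
      mm_out[r] = best_mm;
      rev_strand[r] = best_ori == 1;
      int margin = second_mm - best_mm;
      mapq[r] = second_mm > max_mm ? 60 : (margin >= 2 ? 60 : (margin == 1 ? 20 : 0));
    }
  }
  return DataFrame::create(
      _["mapped"] = mapped, _["contig"] = contig, _["pos"] = pos,
      _["rev"] = rev_strand, _["mismatches"] = mm_out, _["mapq"] = mapq,
      _["stringsAsFactors"] = false);
}
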