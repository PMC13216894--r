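#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include "dna.h"

using namespace Rcpp;

/* Minimal de Bruijn unitig assembler on canonical k-mers.
   Nodes are canonical k-mers with count >= min_count; unitigs are maximal
   non-branching paths (unique successor whose unique predecessor is the
   current node).  Seeds are visited in ascending canonical code order, so
   output is deterministic. */

struct Dbg {
  int k;
  uint64_t mask;
  std::unordered_set<uint64_t> solid; /* canonical codes */

  bool has(uint64_t oriented) const {
    return solid.count(canonical_code(oriented, k)) > 0;
  }
  /* successors of an oriented k-mer (append one base) */
  int succ(uint64_t x, uint64_t *out) const {
    int n = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t y = ((x << 2) | b) & mask;
      if (has(y)) out[n++] = y;
    }
    return n;
  }
  /* in-degree of oriented x = out-degree of its reverse complement */
  int indeg(uint64_t x) const {
    uint64_t tmp[4];
    return succ(revcomp_code(x, k), tmp);
  }
};

/* Walk forward from oriented `start` through non-branching nodes, appending
   bases to `ext` and canonical codes to `path`. */
static void walk(const Dbg &g, uint64_t start,
                 const std::unordered_set<uint64_t> &visited,
                 std::unordered_set<uint64_t> &path, std::string &ext) {
  uint64_t cur = start;
  uint64_t nxt[4];
  for (;;) {
    if (g.succ(cur, nxt) != 1) return;
    uint64_t n = nxt[0];
    if (g.indeg(n) != 1) return;
    uint64_t cn = canonical_code(n, g.k);
    if (visited.count(cn) || path.count(cn)) return;
    path.insert(cn);
    ext.push_back(bits2base((int)(n & 3ULL)));
    cur = n;
  }
}

// [[Rcpp::export]]
CharacterVector cpp_assemble(CharacterVector seqs, int k, int min_count) {
  if (k < 3 || k > 31 || k % 2 == 0) stop("k must be odd and between 3 and 31");
  Dbg g;
  g.k = k;
  g.mask = kmer_mask(k);
  {
    std::unordered_map<uint64_t, int> counts;
    const int shift = 2 * (k - 1);
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
      std::string s = as<std::string>(seqs[i]);
      uint64_t fwd = 0, rev = 0;
      int run = 0;
      for (size_t j = 0; j < s.size(); ++j) {
        int b = base2bits(s[j]);
        if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & g.mask;
        rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
        if (++run >= k) ++counts[fwd < rev ? fwd : rev];
      }
    }
    for (auto &kv : counts)
      if (kv.second >= min_count) g.solid.insert(kv.first);
  }

  std::vector<uint64_t> seeds(g.solid.begin(), g.solid.end());
  std::sort(seeds.begin(), seeds.end());
  std::unordered_set<uint64_t> visited;
  std::vector<std::string> unitigs;

  for (uint64_t c : seeds) {
    if (visited.count(c)) continue;
    std::unordered_set<uint64_t> path;
    path.insert(c);
    std::string fwd_ext, bwd_ext;
    walk(g, c, visited, path, fwd_ext);
    walk(g, revcomp_code(c, k), visited, path, bwd_ext);
    /* unitig = rc(backward extension) + seed + forward extension */
    std::string left(bwd_ext.rbegin(), bwd_ext.rend());
    for (char &ch : left) ch = bits2base(3 - base2bits(ch));
    std::string seq = left + decode_kmer(c, k) + fwd_ext;
    for (uint64_t cc : path) visited.insert(cc);
    unitigs.push_back(seq);
  }
  return wrap(unitigs);
}
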