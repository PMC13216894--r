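#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <queue>
#include <algorithm>
#include "dna.h"

using namespace Rcpp;

/* Visit every canonical k-mer of `seq` (N resets the window) and call f(code). */
template <typename F>
static void for_each_canonical(const std::string &seq, int k, F f) {
  const uint64_t mask = kmer_mask(k);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= k) f(fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export]]
DataFrame cpp_kmer_counts(CharacterVector seqs, int k, int min_count) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_map<uint64_t, int> counts;
  counts.reserve(1 << 16);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for_each_canonical(s, k, [&](uint64_t c) { ++counts[c]; });
  }
  std::vector<std::pair<uint64_t, int>> keep;
  keep.reserve(counts.size());
  for (auto &kv : counts)
    if (kv.second >= min_count) keep.push_back(kv);
  std::sort(keep.begin(), keep.end());
  CharacterVector kmer(keep.size());
  IntegerVector count(keep.size());
  for (size_t i = 0; i < keep.size(); ++i) {
    kmer[i] = decode_kmer(keep[i].first, k);
    count[i] = keep[i].second;
  }
  return DataFrame::create(_["kmer"] = kmer, _["count"] = count,
                           _["stringsAsFactors"] = false);
}

/* Distinct canonical k-mers of a set of sequences, lexicographically sorted. */
// [[Rcpp::export]]
CharacterVector cpp_distinct_kmers(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_set<uint64_t> seen;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for_each_canonical(s, k, [&](uint64_t c) { seen.insert(c); });
  }
  std::vector<uint64_t> v(seen.begin(), seen.end());
  std::sort(v.begin(), v.end());
  CharacterVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = decode_kmer(v[i], k);
  return out;
}

/* Hash explicit k-mer strings (canonicalized first); NA for k-mers containing N. */
// [[Rcpp::export]]
NumericVector cpp_hash_kmers(CharacterVector kmers, int seed) {
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    int k = (int)s.size();
    if (k < 1 || k > 31) stop("k-mer length must be between 1 and 31");
    uint64_t code = 0;
    bool ok = true;
    for (char c : s) {
      int b = base2bits(c);
      if (b < 0) { ok = false; break; }
      code = (code << 2) | (uint64_t)b;
    }
    out[i] = ok
      ? (double)hash_kmer_code(canonical_code(code, k), (uint64_t)seed)
      : NA_REAL;
  }
  return out;
}

/* Bottom-s MinHash sketch: the s smallest distinct 53-bit hashes of all
   canonical k-mers, ascending.  Max-heap + membership set keeps memory at s. */
// [[Rcpp::export]]
NumericVector cpp_sketch(CharacterVector seqs, int k, double s_size, int seed) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  size_t s = (size_t)s_size;
  std::priority_queue<uint64_t> heap;
  std::unordered_set<uint64_t> members;
  members.reserve(std::min<size_t>(s * 2, 1 << 20));
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string seq = as<std::string>(seqs[i]);
    for_each_canonical(seq, k, [&](uint64_t c) {
      uint64_t h = hash_kmer_code(c, (uint64_t)seed);
      if (heap.size() >= s && h >= heap.top()) return;
      if (!members.insert(h).second) return;
      heap.push(h);
      if (heap.size() > s) {
        members.erase(heap.top());
        heap.pop();
      }
    });
  }
  std::vector<uint64_t> v;
  v.reserve(heap.size());
  while (!heap.empty()) { v.push_back(heap.top()); heap.pop(); }
  std::sort(v.begin(), v.end());
  NumericVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = (double)v[i];
  return out;
}
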