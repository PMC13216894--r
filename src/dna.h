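#ifndef COVMARK_DNA_H
#define COVMARK_DNA_H

#include <cstdint>
#include <string>

inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1; /* N or anything else: invalid */
}

inline char bits2base(int b) { return "ACGT"[b & 3]; }

inline uint64_t kmer_mask(int k) {
  return (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
}

/* reverse complement of a 2-bit packed k-mer */
inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

/* 2-bit encoding is alphabetical (A<C<G<T), so numeric min == lexicographic min */
inline uint64_t canonical_code(uint64_t code, int k) {
  uint64_t rc = revcomp_code(code, k);
  return code < rc ? code : rc;
}

inline std::string decode_kmer(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bits2base((int)(code & 3ULL));
    code >>= 2;
  }
  return s;
}

/* splitmix64 finalizer; output masked to 53 bits so values are exact doubles */
inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

inline uint64_t hash_kmer_code(uint64_t code, uint64_t seed) {
  return mix64(code ^ (seed * 0xFF51AFD7ED558CCDULL)) & ((1ULL << 53) - 1);
}

#endif
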