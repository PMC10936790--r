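#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// splitmix64 finalizer: a well-mixed, platform-independent 64-bit hash.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// 2-bit base codes; -1 marks non-ACGT. Big-endian packing preserves
// lexicographic order, so numeric min(code, rc_code) is the canonical k-mer.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Enumerate distinct canonical k-mers of a set of sequences, hash each with
// a seeded 64-bit mix, truncate hashes to 53 bits (exactly representable in
// an R double), and return the s smallest together with the distinct k-mer
// count.  k is limited to 31 so a k-mer packs into one 64-bit word.
// [[Rcpp::export]]
List sketch_kmers_cpp(CharacterVector sequences, int k, int s, double hash_seed) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  if (s < 1) stop("sketch capacity s must be >= 1");
  const uint64_t seed = (uint64_t) hash_seed;
  const uint64_t mask = (k == 31) ? ((1ULL << 62) - 1) : ((1ULL << (2 * k)) - 1);
  const int shift_rc = 2 * (k - 1);

  std::unordered_set<uint64_t> canon;
  bool any_long_enough = false;

  for (int i = 0; i < sequences.size(); ++i) {
    const char* seq = CHAR(STRING_ELT(sequences, i));
    int len = LENGTH(STRING_ELT(sequences, i));
    if (len >= k) any_long_enough = true;
    uint64_t fwd = 0, rc = 0;
    int run = 0; // valid bases accumulated in current window
    for (int p = 0; p < len; ++p) {
      int c = base_code(seq[p]);
      if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t) c) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - c) << shift_rc);
      if (++run >= k) canon.insert(fwd < rc ? fwd : rc);
    }
  }

  std::vector<uint64_t> hashes;
  hashes.reserve(canon.size());
  const uint64_t mask53 = (1ULL << 53) - 1;
  for (uint64_t code : canon) hashes.push_back(mix64(code ^ seed) & mask53);
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  if ((int) hashes.size() > s) hashes.resize(s);

  NumericVector out(hashes.size());
  for (size_t i = 0; i < hashes.size(); ++i) out[i] = (double) hashes[i];
  return List::create(_["hashes"] = out,
                      _["n_kmers"] = (double) canon.size(),
                      _["any_long_enough"] = any_long_enough);
}
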