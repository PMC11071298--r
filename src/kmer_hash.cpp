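#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Canonical k-mer hashing.
//
// Each k-mer is packed into a 2-bit-per-base unsigned 64-bit code (A=0, C=1,
// G=2, T=3), together with the code of its reverse complement, both maintained
// incrementally so the whole scan is O(n). The canonical hash of a position is
// min(mix(fwd), mix(rc)), where mix() is the MurmurHash3 64-bit finalizer
// seeded by XOR with a caller-supplied seed. Hashes are truncated to their low
// 53 bits so they remain exactly representable as R doubles; the low bits are
// kept intact because modimizer membership tests them (hash mod 2^d == 0).
//
// Positions whose window contains a non-ACGT character yield NA (invalid).

static inline uint64_t fmix64(uint64_t h) {
  h ^= h >> 33;
  h *= 0xff51afd7ed558ccdULL;
  h ^= h >> 33;
  h *= 0xc4ceb9fe1a85ec53ULL;
  h ^= h >> 33;
  return h;
}

static const uint64_t HASH_MASK = (1ULL << 53) - 1;  // doubles are exact here

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// [[Rcpp::export(name = ".canonical_hashes_cpp")]]
NumericVector canonical_hashes_cpp(std::string seq, int k, double seed) {
  int64_t n = (int64_t)seq.size();
  if (k < 1) stop("k must be >= 1");
  if (k > 32) stop("k must be <= 32 (2-bit packed 64-bit k-mer codes)");
  if ((int64_t)k > n) stop("k exceeds sequence length");

  int64_t npos = n - k + 1;
  NumericVector out(npos);
  uint64_t sd = (uint64_t)seed;

  // mask for 2k bits; k == 32 uses the full word
  uint64_t kmask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int shift_rc = 2 * (k - 1);

  uint64_t fwd = 0, rc = 0;
  int64_t last_bad = -1;  // most recent position with a non-ACGT base

  for (int64_t i = 0; i < n; ++i) {
    int code = base_code(seq[i]);
    if (code < 0) {
      last_bad = i;
      code = 0;  // placeholder; positions covering i are masked below
    }
    fwd = ((fwd << 2) | (uint64_t)code) & kmask;
    rc = (rc >> 2) | (((uint64_t)(3 - code)) << shift_rc);
    int64_t pos = i - k + 1;  // k-mer start position completed at base i
    if (pos < 0) continue;
    if (last_bad >= pos) {
      out[pos] = NA_REAL;
    } else {
      uint64_t hf = fmix64(fwd ^ sd) & HASH_MASK;
      uint64_t hr = fmix64(rc ^ sd) & HASH_MASK;
      out[pos] = (double)(hf < hr ? hf : hr);
    }
  }
  return out;
}
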