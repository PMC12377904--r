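// Canonical k-mer hashing and community-wide uniqueness counting.
//
// A k-mer is canonical if it is the lexicographically smaller (byte order,
// which for upper-case A/C/G/T is alphabetical) of the window and its reverse
// complement. Windows containing any character other than A/C/G/T emit
// nothing. Canonical k-mers are hashed with FNV-1a 64-bit, a fixed,
// platform-stable non-cryptographic hash; collisions at desk scale (< 10^7
// distinct k-mers against a 2^64 space) are negligible.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <cstring>
#include <cstdio>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 0;
  }
}

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline uint64_t fnv1a64(const char* s, int n) {
  uint64_t h = 1469598103934665603ULL;
  for (int i = 0; i < n; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  return h;
}

// Reverse complement of seq[pos, pos+k) into buf (no validity checking).
static inline void revcomp_into(const char* seq, int pos, int k, char* buf) {
  for (int i = 0; i < k; ++i) buf[i] = comp_base(seq[pos + k - 1 - i]);
}

// Pointer to the canonical form of the window: the window itself or buf.
static inline const char* canonical_window(const char* seq, int pos, int k,
                                           char* buf) {
  revcomp_into(seq, pos, k, buf);
  return (memcmp(seq + pos, buf, (size_t)k) <= 0) ? seq + pos : buf;
}

// Prefix counts of invalid characters, so window validity is O(1).
static std::vector<int> invalid_prefix(const char* s, int n) {
  std::vector<int> pre((size_t)n + 1, 0);
  for (int i = 0; i < n; ++i) pre[i + 1] = pre[i] + (valid_base(s[i]) ? 0 : 1);
  return pre;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical_kmers(std::string seq, int k) {
  int n = (int)seq.size();
  std::vector<std::string> out;
  if (n >= k) {
    std::vector<int> pre = invalid_prefix(seq.c_str(), n);
    std::vector<char> buf((size_t)k);
    for (int p = 0; p + k <= n; ++p) {
      if (pre[p + k] - pre[p] != 0) continue;
      const char* c = canonical_window(seq.c_str(), p, k, buf.data());
      out.emplace_back(c, (size_t)k);
    }
  }
  return wrap(out);
}

// [[Rcpp::export]]
CharacterVector cpp_canonical_kmer_hashes(std::string seq, int k) {
  int n = (int)seq.size();
  std::vector<std::string> out;
  if (n >= k) {
    std::vector<int> pre = invalid_prefix(seq.c_str(), n);
    std::vector<char> buf((size_t)k);
    char hex[17];
    for (int p = 0; p + k <= n; ++p) {
      if (pre[p + k] - pre[p] != 0) continue;
      const char* c = canonical_window(seq.c_str(), p, k, buf.data());
      uint64_t h = fnv1a64(c, k);
      snprintf(hex, sizeof(hex), "%016llx", (unsigned long long)h);
      out.emplace_back(hex, 16);
    }
  }
  return wrap(out);
}

// Per-sequence count of k-mer positions whose canonical hash occurs exactly
// once across the whole collection (a repeat within one sequence is itself
// non-unique).
// [[Rcpp::export]]
IntegerVector cpp_unique_kmer_counts(CharacterVector seqs, int k) {
  int nseq = seqs.size();
  std::unordered_map<uint64_t, uint32_t> tally;
  tally.reserve(1 << 16);

  // pass 1: multiplicities
  for (int s = 0; s < nseq; ++s) {
    const char* str = CHAR(STRING_ELT(seqs, s));
    int n = (int)strlen(str);
    if (n < k) continue;
    std::vector<int> pre = invalid_prefix(str, n);
    std::vector<char> buf((size_t)k);
    for (int p = 0; p + k <= n; ++p) {
      if (pre[p + k] - pre[p] != 0) continue;
      const char* c = canonical_window(str, p, k, buf.data());
      uint32_t& m = tally[fnv1a64(c, k)];
      if (m < 2) ++m;  // cap at 2: only "exactly once" matters
    }
  }

  // pass 2: per-sequence unique counts
  IntegerVector out(nseq);
  for (int s = 0; s < nseq; ++s) {
    const char* str = CHAR(STRING_ELT(seqs, s));
    int n = (int)strlen(str);
    int cnt = 0;
    if (n >= k) {
      std::vector<int> pre = invalid_prefix(str, n);
      std::vector<char> buf((size_t)k);
      for (int p = 0; p + k <= n; ++p) {
        if (pre[p + k] - pre[p] != 0) continue;
        const char* c = canonical_window(str, p, k, buf.data());
        if (tally[fnv1a64(c, k)] == 1) ++cnt;
      }
    }
    out[s] = cnt;
  }
  return out;
}
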