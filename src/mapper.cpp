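// Exact paired-end fragment mapper (seed-and-verify).
//
// A "hit" of a read pair on a reference sequence is an exact, full-length,
// end-to-end match of both mates, on opposite strands in convergent
// (forward-reverse) orientation with non-negative inner gap. A pair is
//   unique    -> all hits fall on exactly one reference (multiple positions on
//                the same reference still count as unique to it),
//   ambiguous -> hits on two or more references,
//   unmapped  -> no hit.
//
// Every SEED_LEN-mer of every reference is indexed (2-bit packed); a mate's
// leading SEED_LEN-mer retrieves candidate positions which are verified by
// full-length comparison, so no perfect hit can be missed. Mates must be
// ACGT-only and at least SEED_LEN long (the read filter guarantees >= 50 b).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <map>
#include <string>
#include <cstdint>
#include <cstring>

using namespace Rcpp;

static const int SEED_LEN = 31;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static inline char comp_base2(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// pack s[pos, pos+SEED_LEN) into 62 bits; false if any non-ACGT
static inline bool pack_seed(const char* s, int pos, uint64_t& key) {
  uint64_t k = 0;
  for (int i = 0; i < SEED_LEN; ++i) {
    int c = base_code(s[pos + i]);
    if (c < 0) return false;
    k = (k << 2) | (uint64_t)c;
  }
  key = k;
  return true;
}

struct RefIndex {
  std::vector<std::string> seqs;
  // seed key -> packed (ref << 32 | pos)
  std::unordered_multimap<uint64_t, uint64_t> pos;
};

static void build_index(const CharacterVector& refs, RefIndex& idx) {
  int nref = refs.size();
  idx.seqs.resize(nref);
  size_t total = 0;
  for (int r = 0; r < nref; ++r) {
    idx.seqs[r] = std::string(CHAR(STRING_ELT(refs, r)));
    if ((int)idx.seqs[r].size() >= SEED_LEN)
      total += idx.seqs[r].size() - SEED_LEN + 1;
  }
  idx.pos.reserve(total);
  for (int r = 0; r < nref; ++r) {
    const std::string& s = idx.seqs[r];
    int n = (int)s.size();
    uint64_t key;
    for (int p = 0; p + SEED_LEN <= n; ++p) {
      if (pack_seed(s.c_str(), p, key))
        idx.pos.emplace(key, ((uint64_t)r << 32) | (uint32_t)p);
    }
  }
}

// all (ref, pos) where `mate` matches exactly and full-length
static void full_matches(const RefIndex& idx, const std::string& mate,
                         std::vector<std::pair<int, int> >& out) {
  out.clear();
  int len = (int)mate.size();
  if (len < SEED_LEN) return;
  uint64_t key;
  if (!pack_seed(mate.c_str(), 0, key)) return;
  auto range = idx.pos.equal_range(key);
  for (auto it = range.first; it != range.second; ++it) {
    int r = (int)(it->second >> 32);
    int p = (int)(uint32_t)it->second;
    const std::string& ref = idx.seqs[r];
    if (p + len > (int)ref.size()) continue;
    if (memcmp(ref.c_str() + p, mate.c_str(), (size_t)len) == 0)
      out.emplace_back(r, p);
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[i] = comp_base2(s[s.size() - 1 - i]);
  return out;
}

struct RefHits {
  int min_f1, max_r1, min_f2, max_r2;
  bool f1, r1, f2, r2;
  RefHits() : min_f1(0), max_r1(0), min_f2(0), max_r2(0),
              f1(false), r1(false), f2(false), r2(false) {}
};

// verdict per pair: 1-based ref index if unique, -1 ambiguous, 0 unmapped
// [[Rcpp::export]]
IntegerVector cpp_map_fragments(CharacterVector refs, CharacterVector r1,
                                CharacterVector r2) {
  if (r1.size() != r2.size()) stop("r1 and r2 must have equal length");
  RefIndex idx;
  build_index(refs, idx);

  int npair = r1.size();
  IntegerVector verdict(npair);
  std::vector<std::pair<int, int> > hits;

  for (int i = 0; i < npair; ++i) {
    std::string a(CHAR(STRING_ELT(r1, i)));
    std::string b(CHAR(STRING_ELT(r2, i)));
    int la = (int)a.size(), lb = (int)b.size();
    std::string rca = revcomp_str(a), rcb = revcomp_str(b);

    std::map<int, RefHits> per_ref;
    full_matches(idx, a, hits);
    for (auto& h : hits) {
      RefHits& rh = per_ref[h.first];
      if (!rh.f1 || h.second < rh.min_f1) rh.min_f1 = h.second;
      rh.f1 = true;
    }
    full_matches(idx, rca, hits);
    for (auto& h : hits) {
      RefHits& rh = per_ref[h.first];
      if (!rh.r1 || h.second > rh.max_r1) rh.max_r1 = h.second;
      rh.r1 = true;
    }
    full_matches(idx, b, hits);
    for (auto& h : hits) {
      RefHits& rh = per_ref[h.first];
      if (!rh.f2 || h.second < rh.min_f2) rh.min_f2 = h.second;
      rh.f2 = true;
    }
    full_matches(idx, rcb, hits);
    for (auto& h : hits) {
      RefHits& rh = per_ref[h.first];
      if (!rh.r2 || h.second > rh.max_r2) rh.max_r2 = h.second;
      rh.r2 = true;
    }

    int hit_ref = -1;
    int nrefs_hit = 0;
    for (auto& kv : per_ref) {
      const RefHits& rh = kv.second;
      // convergent orientation, inner gap >= 0
      bool proper = (rh.f1 && rh.r2 && rh.max_r2 >= rh.min_f1 + la) ||
                    (rh.f2 && rh.r1 && rh.max_r1 >= rh.min_f2 + lb);
      if (proper) {
        ++nrefs_hit;
        hit_ref = kv.first;
        if (nrefs_hit > 1) break;
      }
    }
    verdict[i] = (nrefs_hit == 0) ? 0 : (nrefs_hit == 1 ? hit_ref + 1 : -1);
  }
  return verdict;
}
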