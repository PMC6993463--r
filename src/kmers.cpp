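// Canonical k-mer counting over a read set. A k-mer and its reverse
// complement are one species (lexicographic minimum kept); windows touching
// an ambiguous base are skipped.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

static inline int base2(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static inline uint64_t rc_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) { rc = (rc << 2) | (3 - (code & 3)); code >>= 2; }
  return rc;
}

static std::string decode(uint64_t code, int k) {
  static const char* B = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = B[code & 3]; code >>= 2; }
  return s;
}

// [[Rcpp::export(name = ".count_canonical_kmers")]]
IntegerVector count_canonical_kmers(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_map<uint64_t, int> counts;
  uint64_t mask = (1ULL << (2 * k)) - 1;
  for (int s = 0; s < seqs.size(); ++s) {
    std::string str = as<std::string>(seqs[s]);
    uint64_t code = 0; int run = 0;
    for (size_t i = 0; i < str.size(); ++i) {
      int b = base2(str[i]);
      if (b > 3) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t) b) & mask;
      if (++run >= k) {
        uint64_t rc = rc_code(code, k);
        ++counts[code < rc ? code : rc];
      }
    }
  }
  IntegerVector out(counts.size());
  CharacterVector nm(counts.size());
  R_xlen_t i = 0;
  for (auto& kv : counts) {
    nm[i] = decode(kv.first, k);
    out[i] = kv.second;
    ++i;
  }
  out.names() = nm;
  return out;
}
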