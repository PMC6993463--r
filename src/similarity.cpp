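// Seed-and-extend ungapped read scorer: a desk-scale stand-in for all-vs-all
// megablast. Exact shared seeds (either strand) anchor ungapped X-drop
// extensions; the best raw score is converted to bits in R.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4; // N and friends: never match, never seed
  }
}

static std::vector<int8_t> encode(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t) base_code(s[i]);
  return v;
}

static std::vector<int8_t> revcomp(const std::vector<int8_t>& v) {
  std::vector<int8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int8_t b = v[v.size() - 1 - i];
    r[i] = (b < 4) ? (int8_t)(3 - b) : (int8_t)4;
  }
  return r;
}

// all valid (N-free) seeds of length k as 2-bit codes, with positions
static void seeds_of(const std::vector<int8_t>& v, int k,
                     std::vector<uint64_t>& codes, std::vector<int>& pos) {
  codes.clear(); pos.clear();
  if ((int) v.size() < k) return;
  uint64_t code = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0; // valid bases accumulated
  for (size_t i = 0; i < v.size(); ++i) {
    if (v[i] > 3) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t) v[i]) & mask;
    if (++run >= k) { codes.push_back(code); pos.push_back((int)(i) - k + 1); }
  }
}

static inline uint64_t rc_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) { rc = (rc << 2) | (3 - (code & 3)); code >>= 2; }
  return rc;
}

// ungapped X-drop extension around an exact seed at a[ai..ai+k), b[bi..bi+k)
static int extend_anchor(const std::vector<int8_t>& a, const std::vector<int8_t>& b,
                         int ai, int bi, int k, int match, int mismatch, int xdrop) {
  int score = k * match;
  // right
  {
    int run = 0, best = 0;
    int i = ai + k, j = bi + k;
    while (i < (int) a.size() && j < (int) b.size()) {
      run += (a[i] < 4 && a[i] == b[j]) ? match : mismatch;
      if (run > best) best = run;
      if (best - run >= xdrop) break;
      ++i; ++j;
    }
    score += best;
  }
  // left
  {
    int run = 0, best = 0;
    int i = ai - 1, j = bi - 1;
    while (i >= 0 && j >= 0) {
      run += (a[i] < 4 && a[i] == b[j]) ? match : mismatch;
      if (run > best) best = run;
      if (best - run >= xdrop) break;
      --i; --j;
    }
    score += best;
  }
  return score;
}

// best raw score between a and b (both strands); -1 if no shared seed
static int best_raw(const std::vector<int8_t>& a, const std::vector<int8_t>& b,
                    int k, int match, int mismatch, int xdrop) {
  std::vector<uint64_t> ca, cb; std::vector<int> pa, pb;
  seeds_of(a, k, ca, pa);
  if (ca.empty()) return -1;
  std::unordered_multimap<uint64_t, int> idx;
  idx.reserve(ca.size() * 2);
  for (size_t i = 0; i < ca.size(); ++i) idx.emplace(ca[i], pa[i]);
  int best = -1;
  const std::vector<int8_t>* bs[2];
  std::vector<int8_t> brc = revcomp(b);
  bs[0] = &b; bs[1] = &brc;
  for (int strand = 0; strand < 2; ++strand) {
    seeds_of(*bs[strand], k, cb, pb);
    // one extension per diagonal and strand is not enough for exactness under
    // X-drop, so extend every anchor; reads are short and this stays cheap
    std::unordered_set<int64_t> seen; // (diag) -> skip repeated identical anchors on same diagonal only when seed-adjacent
    for (size_t j = 0; j < cb.size(); ++j) {
      auto range = idx.equal_range(cb[j]);
      for (auto it = range.first; it != range.second; ++it) {
        int s = extend_anchor(a, *bs[strand], it->second, pb[j], k, match, mismatch, xdrop);
        if (s > best) best = s;
      }
    }
  }
  return best;
}

// [[Rcpp::export(name = ".score_pair_raw")]]
int score_pair_raw(std::string a, std::string b, int seed_length,
                   int match, int mismatch, int xdrop) {
  if (a.empty() || b.empty()) stop("empty sequence");
  std::vector<int8_t> ea = encode(a), eb = encode(b);
  return best_raw(ea, eb, seed_length, match, mismatch, xdrop);
}

// All-vs-all: candidate pairs share at least one canonical seed; each
// candidate is scored with the same per-pair routine as .score_pair_raw,
// so the result equals brute-force scoring of every pair.
// [[Rcpp::export(name = ".all_vs_all_raw")]]
DataFrame all_vs_all_raw(CharacterVector seqs, int seed_length,
                         int match, int mismatch, int xdrop, int min_raw) {
  int n = seqs.size();
  std::vector<std::vector<int8_t>> enc(n);
  for (int i = 0; i < n; ++i) enc[i] = encode(as<std::string>(seqs[i]));

  // canonical seed -> reads containing it (forward strand scan suffices:
  // canonical form collapses the two strands)
  std::unordered_map<uint64_t, std::vector<int>> index;
  std::vector<uint64_t> codes; std::vector<int> pos;
  for (int i = 0; i < n; ++i) {
    seeds_of(enc[i], seed_length, codes, pos);
    std::unordered_set<uint64_t> mine;
    for (uint64_t c : codes) {
      uint64_t rc = rc_code(c, seed_length);
      mine.insert(c < rc ? c : rc);
    }
    for (uint64_t c : mine) index[c].push_back(i);
  }

  std::unordered_set<int64_t> cand;
  for (auto& kv : index) {
    const std::vector<int>& v = kv.second;
    if (v.size() < 2) continue;
    for (size_t x = 0; x + 1 < v.size(); ++x)
      for (size_t y = x + 1; y < v.size(); ++y)
        cand.insert((int64_t) v[x] * n + v[y]);
  }

  std::vector<int> ia, ib, raw;
  std::vector<int64_t> keys(cand.begin(), cand.end());
  std::sort(keys.begin(), keys.end());
  for (int64_t key : keys) {
    int i = (int)(key / n), j = (int)(key % n);
    int s = best_raw(enc[i], enc[j], seed_length, match, mismatch, xdrop);
    if (s >= min_raw) { ia.push_back(i + 1); ib.push_back(j + 1); raw.push_back(s); }
  }
  return DataFrame::create(_["i"] = ia, _["j"] = ib, _["raw"] = raw);
}
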