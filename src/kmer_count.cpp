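#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding A=0, C=1, G=2, T=3 preserves lexicographic order for
// fixed-length words, so the numeric minimum of a code and its
// reverse-complement code is the canonical k-mer.

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;  // N or any non-ACGT: breaks the window
  }
}

static std::string decode_kmer(uint64_t code, int k) {
  static const char bases[] = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bases[code & 3ULL];
    code >>= 2;
  }
  return s;
}

static uint64_t encode_kmer(const std::string& s) {
  uint64_t code = 0;
  for (char c : s) code = (code << 2) | (uint64_t) base_code(c);
  return code;
}

// Stream canonical codes of all valid (N-free) windows of `seq` into `f`.
template <typename F>
static void roll(const std::string& seq, int k, F f) {
  const size_t L = seq.size();
  if ((size_t) k > L) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int run = 0;  // length of current N-free run
  for (size_t i = 0; i < L; ++i) {
    int b = base_code(seq[i]);
    if (b < 0) { run = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t) b) & mask;
    rc = (rc >> 2) | ((uint64_t) (3 - b) << shift);
    if (++run >= k) f(fwd < rc ? fwd : rc);
  }
}

// [[Rcpp::export]]
IntegerVector cpp_count_kmers(std::string seq, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_map<uint64_t, int> tab;
  roll(seq, k, [&](uint64_t c) { ++tab[c]; });
  std::vector<std::pair<uint64_t, int>> v(tab.begin(), tab.end());
  std::sort(v.begin(), v.end());
  IntegerVector out(v.size());
  CharacterVector nm(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    out[i] = v[i].second;
    nm[i] = decode_kmer(v[i].first, k);
  }
  out.attr("names") = nm;
  return out;
}

// Canonical k-mers whose summed count over all sequences is >= min_total,
// in lexicographic order. One hash over the whole genome; used as the
// pruning pass so per-chromosome matrices are only built for survivors.
// [[Rcpp::export]]
CharacterVector cpp_high_copy_kmers(CharacterVector seqs, int k, double min_total) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_map<uint64_t, int> tab;
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    std::string s = as<std::string>(seqs[j]);
    roll(s, k, [&](uint64_t c) { ++tab[c]; });
  }
  std::vector<uint64_t> keep;
  for (auto& kv : tab)
    if (kv.second >= min_total) keep.push_back(kv.first);
  std::sort(keep.begin(), keep.end());
  CharacterVector out(keep.size());
  for (size_t i = 0; i < keep.size(); ++i) out[i] = decode_kmer(keep[i], k);
  return out;
}

// Counts of a fixed set of canonical k-mers in one sequence (same order).
// [[Rcpp::export]]
IntegerVector cpp_count_restricted(std::string seq, int k, CharacterVector kmers) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_map<uint64_t, int> idx;
  idx.reserve(kmers.size() * 2);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int) s.size() != k) stop("k-mer length does not match k");
    idx[encode_kmer(s)] = (int) i;
  }
  IntegerVector out(kmers.size());
  roll(seq, k, [&](uint64_t c) {
    auto it = idx.find(c);
    if (it != idx.end()) ++out[it->second];
  });
  return out;
}
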