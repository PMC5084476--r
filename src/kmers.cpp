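#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit encoded k-mer counting, k <= 31 (2k bits must fit in 62).
// Canonical counting stores min(forward, reverse-complement) encoding,
// matching strand-random sequencing reads.

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

typedef std::unordered_map<uint64_t, int> kmap;

static void add_seq_kmers(const char *s, int n, int k, bool canonical, kmap &map) {
  uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (int i = 0; i < n; i++) {
    int b = base2bits(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++valid >= k) {
      uint64_t key = canonical ? (fwd < rev ? fwd : rev) : fwd;
      map[key]++;
    }
  }
}

static kmap build_map(const CharacterVector &seqs, int k, bool canonical) {
  kmap map;
  map.reserve(1 << 16);
  for (R_xlen_t i = 0; i < seqs.size(); i++) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    add_seq_kmers(s, (int)LENGTH(STRING_ELT(seqs, i)), k, canonical, map);
  }
  return map;
}

static std::string decode(uint64_t code, int k) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string out(k, 'N');
  for (int i = k - 1; i >= 0; i--) {
    out[i] = bases[code & 3ULL];
    code >>= 2;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k, bool canonical, bool return_kmers) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  kmap map = build_map(seqs, k, canonical);
  R_xlen_t n = (R_xlen_t)map.size();
  IntegerVector counts(n);
  CharacterVector kmers(return_kmers ? n : 0);
  R_xlen_t i = 0;
  for (kmap::const_iterator it = map.begin(); it != map.end(); ++it, ++i) {
    counts[i] = it->second;
    if (return_kmers) kmers[i] = decode(it->first, k);
  }
  if (return_kmers) return List::create(_["kmer"] = kmers, _["count"] = counts);
  return List::create(_["count"] = counts);
}

// Per-position abundance (in `reads`) of the k-mer starting at each position
// of `assembly`. If circular, the track wraps (length == nchar(assembly)).
// [[Rcpp::export]]
IntegerVector cpp_position_abundance(std::string assembly, CharacterVector reads,
                                     int k, bool canonical, bool circular) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  int n = (int)assembly.size();
  if (n < k) stop("assembly shorter than k");
  kmap map = build_map(reads, k, canonical);
  std::string s = assembly;
  if (circular) s += assembly.substr(0, k - 1);
  int out_len = circular ? n : n - k + 1;
  IntegerVector out(out_len);
  uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (int i = 0; i < (int)s.size(); i++) {
    int b = base2bits(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++valid >= k) {
      int pos = i - k + 1;  // 0-based start of this k-mer
      if (pos < out_len) {
        uint64_t key = canonical ? (fwd < rev ? fwd : rev) : fwd;
        kmap::const_iterator it = map.find(key);
        out[pos] = (it == map.end()) ? 0 : it->second;
      }
    }
  }
  return out;
}
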