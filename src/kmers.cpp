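#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit base encoding; -1 for anything that is not A/C/G/T.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char DECODE[4] = {'A', 'C', 'G', 'T'};

// Reverse complement of a 2-bit packed k-mer (complement = 3 - code).
static inline uint64_t revcomp_code(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return r;
}

// Count canonical k-mers over a set of reads. k-mers containing a non-ACGT
// character are skipped. Canonical form = min(code, revcomp code), which for
// the lexicographic ordering of A<C<G<T strings coincides with numeric order
// of the 2-bit packing. Output is sorted by encoded value (i.e. by k-mer
// string) so results are deterministic across runs.
// [[Rcpp::export(name = ".count_kmers_cpp")]]
List count_kmers_cpp(CharacterVector reads, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_map<uint64_t, double> tab;
  tab.reserve(1 << 20);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  double total = 0.0;

  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    if (reads[r] == NA_STRING) continue;
    const char *s = CHAR(STRING_ELT(reads, r));
    int valid = 0;          // length of current run of ACGT characters
    uint64_t fwd = 0;
    for (const char *p = s; *p; ++p) {
      int c = base_code(*p);
      if (c < 0) { valid = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        uint64_t rc = revcomp_code(fwd, k);
        uint64_t canon = fwd < rc ? fwd : rc;
        tab[canon] += 1.0;
        total += 1.0;
      }
    }
  }

  std::vector<uint64_t> keys;
  keys.reserve(tab.size());
  for (auto &kv : tab) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());

  R_xlen_t n = (R_xlen_t)keys.size();
  CharacterVector kmers(n);
  NumericVector counts(n);
  std::vector<char> buf(k + 1);
  buf[k] = '\0';
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t x = keys[i];
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = DECODE[x & 3ULL];
      x >>= 2;
    }
    kmers[i] = &buf[0];
    counts[i] = tab[keys[i]];
  }
  return List::create(_["kmer"] = kmers, _["count"] = counts,
                      _["total"] = total);
}

// All positions (1-based) where `primer` matches `template_seq` with at most
// max_mismatch substitutions and an exact match over the 3'-terminal
// `anchor` bases. Brute-force sliding window; templates here are tandem-array
// sized (a few kb) so this is plenty fast.
// [[Rcpp::export(name = ".primer_scan_cpp")]]
IntegerVector primer_scan_cpp(std::string template_seq, std::string primer,
                              int max_mismatch, int anchor) {
  int n = (int)template_seq.size(), m = (int)primer.size();
  std::vector<int> hits;
  if (m > n) return IntegerVector(0);
  for (int i = 0; i + m <= n; ++i) {
    int mm = 0;
    bool ok = true;
    for (int j = 0; j < m; ++j) {
      if (template_seq[i + j] != primer[j]) {
        if (j >= m - anchor) { ok = false; break; }
        if (++mm > max_mismatch) { ok = false; break; }
      }
    }
    if (ok) hits.push_back(i + 1);
  }
  return IntegerVector(hits.begin(), hits.end());
}
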