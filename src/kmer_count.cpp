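#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes; -1 marks non-ACGT (window is skipped)
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Count canonical k-mers (lexicographic min of k-mer and reverse complement)
// across a set of sequences. Returns the multiplicity histogram.
// [[Rcpp::export]]
List count_canonical_kmers(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_map<uint64_t, uint32_t> counts;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift_rc = 2 * (k - 1);
  double total = 0.0;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *str = CHAR(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rc = 0;
    int valid = 0;  // number of consecutive valid bases ending here
    for (const char *p = str; *p; ++p) {
      int c = base_code(*p);
      if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - c) << shift_rc);
      if (++valid >= k) {
        uint64_t canon = fwd < rc ? fwd : rc;
        ++counts[canon];
        total += 1.0;
      }
    }
  }
  if (counts.empty())
    stop("no k-mer windows: k larger than every valid stretch");
  std::unordered_map<uint32_t, double> hist;
  for (auto &kv : counts) hist[kv.second] += 1.0;
  std::vector<uint32_t> mult;
  mult.reserve(hist.size());
  for (auto &kv : hist) mult.push_back(kv.first);
  std::sort(mult.begin(), mult.end());
  IntegerVector multiplicity(mult.size());
  NumericVector n_kmers(mult.size());
  for (size_t i = 0; i < mult.size(); ++i) {
    multiplicity[i] = (int)mult[i];
    n_kmers[i] = hist[mult[i]];
  }
  return List::create(_["multiplicity"] = multiplicity,
                      _["n_kmers"] = n_kmers,
                      _["total_kmers"] = total,
                      _["distinct_kmers"] = (double)counts.size());
}
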