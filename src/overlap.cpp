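#include <Rcpp.h>
#include <string>

using namespace Rcpp;

// Best ungapped suffix(a)-prefix(b) overlap of length >= min_overlap.
// Returns c(L, mismatches) minimizing mismatch fraction, ties to larger L;
// c(0, 0) when no overlap of the required length exists.
//
// [[Rcpp::export(name = ".best_overlap")]]
IntegerVector best_overlap(std::string a, std::string b, int min_overlap) {
  const int na = (int) a.size(), nb = (int) b.size();
  const int lmax = std::min(na, nb);
  int best_l = 0, best_mm = 0;
  double best_frac = 2.0;
  for (int L = min_overlap; L <= lmax; ++L) {
    int mm = 0;
    const int off = na - L;
    for (int k = 0; k < L; ++k) {
      if (a[(size_t)(off + k)] != b[(size_t) k]) ++mm;
    }
    double frac = (double) mm / (double) L;
    if (frac < best_frac || (frac == best_frac && L > best_l)) {
      best_frac = frac;
      best_l = L;
      best_mm = mm;
    }
  }
  return IntegerVector::create(best_l, best_mm);
}
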