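#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman-Gotoh).
// A gap of length L costs gap_open + L * gap_extend (open charged once).
// Traceback tie-breaking: diagonal over up (query-consuming) over left
// (reference-consuming); the traceback starts from the rightmost maximal
// cell (largest reference column, then largest query row).
//
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string query, std::string ref,
              double match, double mismatch,
              double gap_open, double gap_extend) {
  const int n = (int) query.size();
  const int m = (int) ref.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const double NEG = -1e30;

  // H: best score ending at (i, j); E: ending with gap in reference
  // (consumes query, "up"); F: ending with gap in query (consumes ref,
  // "left"). Row-major (m + 1) columns.
  std::vector<double> H((size_t)(n + 1) * (m + 1), 0.0);
  std::vector<double> E((size_t)(n + 1) * (m + 1), NEG);
  std::vector<double> F((size_t)(n + 1) * (m + 1), NEG);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char qc = query[(size_t) i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t idx = (size_t) i * (m + 1) + j;
      const size_t up = idx - (size_t)(m + 1);
      const size_t left = idx - 1;
      double e = std::max(H[up] + gap_open + gap_extend, E[up] + gap_extend);
      double f = std::max(H[left] + gap_open + gap_extend, F[left] + gap_extend);
      double s = (qc == ref[(size_t) j - 1]) ? match : mismatch;
      double h = H[idx - (size_t)(m + 1) - 1] + s;
      h = std::max(h, std::max(e, f));
      if (h < 0) h = 0;
      E[idx] = e;
      F[idx] = f;
      H[idx] = h;
      // rightmost maximal cell: strictly greater score, or equal score at a
      // larger column, or equal score and column at a larger row
      if (h > best || (h == best && (j > bj || (j == bj && i > bi)))) {
        if (h > 0) { best = h; bi = i; bj = j; }
      }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["r_start"] = NA_INTEGER,
                        _["r_end"] = NA_INTEGER, _["q_aln"] = "",
                        _["r_aln"] = "");
  }

  // traceback from (bi, bj) until a zero H cell
  std::string qa, ra;
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E (up), 2 = F (left)
  while (i > 0 && j > 0) {
    const size_t idx = (size_t) i * (m + 1) + j;
    if (state == 0) {
      if (H[idx] == 0) break;
      double s = (query[(size_t) i - 1] == ref[(size_t) j - 1]) ? match : mismatch;
      if (H[idx] == H[idx - (size_t)(m + 1) - 1] + s) {
        qa.push_back(query[(size_t) i - 1]);
        ra.push_back(ref[(size_t) j - 1]);
        --i; --j;
      } else if (H[idx] == E[idx]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      const size_t up = idx - (size_t)(m + 1);
      qa.push_back(query[(size_t) i - 1]);
      ra.push_back('-');
      bool from_h = (E[idx] == H[up] + gap_open + gap_extend);
      --i;
      state = from_h ? 0 : 1;
    } else {
      const size_t left = idx - 1;
      qa.push_back('-');
      ra.push_back(ref[(size_t) j - 1]);
      bool from_h = (F[idx] == H[left] + gap_open + gap_extend);
      --j;
      state = from_h ? 0 : 2;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ra.begin(), ra.end());

  return List::create(_["score"] = best,
                      _["q_start"] = i + 1, _["q_end"] = bi,
                      _["r_start"] = j + 1, _["r_end"] = bj,
                      _["q_aln"] = qa, _["r_aln"] = ra);
}
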