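#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with linear gap penalty.
// Tie-breaking: the best-scoring cell with the lowest (q_end, s_end) wins
// (cells scanned in row-major order, strictly greater score to replace);
// traceback prefers diagonal over up (gap in subject) over left (gap in query).
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string query, std::string subject,
              double match = 2.0, double mismatch = -1.0, double gap = -2.0) {
  const int n = query.size(), m = subject.size();
  NumericMatrix H(n + 1, m + 1);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = H(i - 1, j - 1) + (query[i - 1] == subject[j - 1] ? match : mismatch);
      double up = H(i - 1, j) + gap;
      double left = H(i, j - 1) + gap;
      double h = diag;
      if (up > h) h = up;
      if (left > h) h = left;
      if (h < 0.0) h = 0.0;
      H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0,
                        _["matches"] = 0, _["aligned"] = 0);
  }
  // traceback
  int i = bi, j = bj, matches = 0, cols = 0;
  while (i > 0 && j > 0 && H(i, j) > 0.0) {
    double h = H(i, j);
    double sub = (query[i - 1] == subject[j - 1] ? match : mismatch);
    if (H(i - 1, j - 1) + sub == h) {
      if (query[i - 1] == subject[j - 1]) ++matches;
      ++cols; --i; --j;
    } else if (H(i - 1, j) + gap == h) {
      ++cols; --i;
    } else {
      ++cols; --j;
    }
  }
  return List::create(_["score"] = best,
                      _["q_start"] = i + 1, _["q_end"] = bi,
                      _["s_start"] = j + 1, _["s_end"] = bj,
                      _["matches"] = matches, _["aligned"] = cols);
}
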