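#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive linear-trajectory search: for every candidate (origin bin,
// signed speed) sum the windowed posterior mass W(b, j) along the line's
// clipped bin positions. Candidates are scanned speeds-outer (already in
// tie-break order: increasing |speed|, positive first) and origins-inner, and
// only a strictly greater score replaces the incumbent, so the first-best
// tie-break matches the documented rule.
// [[Rcpp::export(name = ".fit_search_cpp")]]
List fit_search_cpp(NumericMatrix W, IntegerMatrix shift) {
  const int nb = W.nrow(), nt = W.ncol(), ns = shift.nrow();
  double best = R_NegInf;
  int best_o = 0, best_s = 0;
  for (int s = 0; s < ns; ++s) {
    for (int o = 0; o < nb; ++o) {
      double sc = 0.0;
      for (int j = 0; j < nt; ++j) {
        int b = o + shift(s, j);
        if (b < 0) b = 0; else if (b >= nb) b = nb - 1;
        sc += W(b, j);
      }
      if (sc > best) { best = sc; best_o = o; best_s = s; }
    }
  }
  return List::create(_["sum"] = best, _["origin"] = best_o + 1,
                      _["speed_idx"] = best_s + 1);
}
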