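#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Greedy nearest-timestamp matching of two time-sorted frame streams.
// For each front timestamp (in order), advances through the side stream
// while the next side frame is at least as close, then matches if within
// tolerance. Each side frame is used at most once. Returns the 1-based
// side index per front frame, 0 when unmatched.
// [[Rcpp::export]]
IntegerVector match_streams_greedy(NumericVector front_t, NumericVector side_t,
                                   double tolerance) {
  const int nf = front_t.size(), ns = side_t.size();
  IntegerVector out(nf, 0);
  int j = 0;
  for (int i = 0; i < nf; ++i) {
    if (j >= ns) break;
    while (j + 1 < ns &&
           std::fabs(side_t[j + 1] - front_t[i]) <= std::fabs(side_t[j] - front_t[i]))
      ++j;
    if (std::fabs(side_t[j] - front_t[i]) <= tolerance) {
      out[i] = j + 1;
      ++j;
    }
  }
  return out;
}
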