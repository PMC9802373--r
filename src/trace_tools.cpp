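// helpers for state segmentation of long filtered traces
#include <Rcpp.h>
using namespace Rcpp;

// Hard assignment of each sample to the nearest level, with hysteresis: the
// current state is kept unless another level is closer by more than `margin`
// (in nm). NA samples (filter edges) stay unassigned. Returns 1-based level
// indices.
// [[Rcpp::export]]
IntegerVector cpp_hysteresis_assign(NumericVector z, NumericVector levels,
                                    double margin) {
  int n = z.size(), m = levels.size();
  IntegerVector out(n);
  int cur = -1;
  for (int t = 0; t < n; ++t) {
    if (NumericVector::is_na(z[t])) {
      out[t] = NA_INTEGER;
      continue;
    }
    int best = 0;
    double bestd = std::fabs(z[t] - levels[0]);
    for (int k = 1; k < m; ++k) {
      double d = std::fabs(z[t] - levels[k]);
      if (d < bestd) {
        bestd = d;
        best = k;
      }
    }
    if (cur < 0) {
      cur = best;
    } else {
      double dcur = std::fabs(z[t] - levels[cur]);
      if (bestd < dcur - margin) cur = best;
    }
    out[t] = cur + 1;
  }
  return out;
}
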