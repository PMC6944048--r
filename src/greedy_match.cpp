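#include <Rcpp.h>
using namespace Rcpp;

// Greedy 1:1 nearest-neighbour caliper matching kernel.
//
// case_scores: propensity scores of cases, already in processing order.
// ctrl_scores: propensity scores of controls, already in tie-break order
//   (equidistant controls are resolved to the earliest position).
// caliper: maximum |score difference| accepted (probability scale).
//
// Returns, for each case in processing order, the 1-based position of the
// matched control in ctrl_scores, or 0 if no unmatched control lies within
// the caliper. Each control is used at most once.
// [[Rcpp::export]]
IntegerVector greedy_match_cpp(NumericVector case_scores,
                               NumericVector ctrl_scores,
                               double caliper) {
  const int nca = case_scores.size();
  const int nco = ctrl_scores.size();
  const double eps = 1e-12;
  std::vector<bool> used(nco, false);
  IntegerVector out(nca);
  for (int i = 0; i < nca; ++i) {
    double best = R_PosInf;
    int bj = -1;
    for (int j = 0; j < nco; ++j) {
      if (used[j]) continue;
      double d = std::fabs(case_scores[i] - ctrl_scores[j]);
      if (d < best - eps) {  // strict improvement: ties keep earliest control
        best = d;
        bj = j;
      }
    }
    if (bj >= 0 && best <= caliper + eps) {
      used[bj] = true;
      out[i] = bj + 1;
    } else {
      out[i] = 0;
    }
  }
  return out;
}
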