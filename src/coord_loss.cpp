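#include <Rcpp.h>
using namespace Rcpp;

// Per-target average GDT-TS loss for every candidate value of one weight
// coordinate. `base` holds the combined score of all other features on the
// quality grid (grid-major, models concatenated in target order), `d` the
// scanned feature's density on the same layout. For each candidate c the
// model's predicted quality is the grid argmax of base + c * d (ties to the
// smallest grid point); each target charges the gap between its best true
// score and the true score of its top-ranked model (ties to the first
// model in table order).
// [[Rcpp::export]]
NumericVector coord_candidate_losses(NumericVector base, NumericVector d,
                                     NumericVector cand, int n_grid,
                                     IntegerVector target_sizes,
                                     NumericVector truths,
                                     NumericVector best_true) {
  const int n_models = base.size() / n_grid;
  const int n_cand = cand.size();
  const int n_targets = target_sizes.size();
  NumericVector losses(n_cand);
  std::vector<int> xhat(n_models);

  for (int c = 0; c < n_cand; ++c) {
    const double cv = cand[c];
    for (int m = 0; m < n_models; ++m) {
      const double *b = &base[(R_xlen_t)m * n_grid];
      const double *dd = &d[(R_xlen_t)m * n_grid];
      double best = b[0] + cv * dd[0];
      int besti = 0;
      for (int g = 1; g < n_grid; ++g) {
        const double v = b[g] + cv * dd[g];
        if (v > best) { best = v; besti = g; }
      }
      xhat[m] = besti;
    }
    double loss_sum = 0.0;
    int m = 0;
    for (int t = 0; t < n_targets; ++t) {
      int pick = m;
      int bestx = -1;
      for (int k = 0; k < target_sizes[t]; ++k, ++m) {
        if (xhat[m] > bestx) { bestx = xhat[m]; pick = m; }
      }
      loss_sum += best_true[t] - truths[pick];
    }
    losses[c] = loss_sum / n_targets;
  }
  return losses;
}
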