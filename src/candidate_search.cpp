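#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Inner candidate screening for the mother-media simulation: draw
// `inner_iters` random m x d level matrices (entries uniform on
// 0..levels-1, via R's RNG exactly as sample() would draw them) and keep
// the one with the smallest penalty
//   H * (#zero-variance cols + #zero-variance rows + #pairs |r|>hard)
//     + #pairs soft<|r|<=hard,  H = d^2 + 1.
// First-encountered minimum wins, matching the R reference path.
// [[Rcpp::export]]
List best_candidate_cpp(const int m, const int d, const int levels,
                        const int inner_iters, const double soft,
                        const double hard) {
  const double H = static_cast<double>(d) * d + 1.0;
  arma::mat best;
  double best_total = R_PosInf;
  int best_zero = 0, best_hard = 0, best_soft = 0;
  for (int it = 0; it < inner_iters; ++it) {
    // identical RNG stream to the R-side floor(runif(m*d) * levels)
    arma::mat vals(m, d);
    for (int j = 0; j < m * d; ++j) {
      int v = static_cast<int>(unif_rand() * levels);
      if (v >= levels) v = levels - 1;
      vals[j] = v;
    }
    const arma::rowvec mu = arma::mean(vals, 0);
    const arma::rowvec cv = arma::mean(arma::square(vals.each_row() - mu), 0);
    const arma::vec rv = arma::mean(arma::square(vals.each_col() - arma::mean(vals, 1)), 1);
    const int zero_var = arma::sum(cv <= 1e-12) + arma::sum(rv <= 1e-12);
    int nhard = 0, nsoft = 0;
    const arma::uvec ok = arma::find(cv > 1e-12);
    if (ok.n_elem >= 2) {
      const arma::mat r = arma::abs(arma::cor(vals.cols(ok)));
      for (arma::uword a = 0; a + 1 < r.n_rows; ++a)
        for (arma::uword b = a + 1; b < r.n_cols; ++b) {
          if (r(a, b) > hard) ++nhard;
          else if (r(a, b) > soft) ++nsoft;
        }
    }
    const double total = H * (zero_var + nhard) + nsoft;
    if (total < best_total) {
      best_total = total; best = vals;
      best_zero = zero_var; best_hard = nhard; best_soft = nsoft;
    }
  }
  return List::create(_["values"] = best, _["zero_variance"] = best_zero,
                      _["hard_pairs"] = best_hard, _["soft_pairs"] = best_soft,
                      _["total"] = best_total);
}
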