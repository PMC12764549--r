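#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Random-subset D-optimal search over the rows of the candidate score
// matrix E (k x p). Each iteration samples n distinct rows uniformly and
// scores them by det(E_sel' E_sel). Uses R's RNG so set.seed() governs
// reproducibility; ties keep the first-encountered subset.
// [[Rcpp::export]]
List dopt_search_cpp(const arma::mat& E, const int n, const int iters,
                     const bool standardize_cols) {
  const int k = E.n_rows;
  NumericVector trace(iters);
  IntegerVector best_idx(n), worst_idx(n);
  double best = R_NegInf, worst = R_PosInf;
  // partial Fisher-Yates over a persistent index pool: O(n) per draw and
  // uniform over n-subsets regardless of the pool's current order
  arma::uvec pool = arma::regspace<arma::uvec>(0, k - 1);
  arma::uvec rows(n);
  for (int it = 0; it < iters; ++it) {
    for (int i = 0; i < n; ++i) {
      int j = i + static_cast<int>(unif_rand() * (k - i));
      if (j >= k) j = k - 1;
      std::swap(pool[i], pool[j]);
      rows[i] = pool[i];
    }
    arma::mat Es = E.rows(rows);
    if (standardize_cols) {
      const arma::rowvec mu = arma::mean(Es, 0);
      // population standard deviation, matching the R-side convention
      const arma::rowvec sdev = arma::sqrt(arma::mean(arma::square(Es.each_row() - mu), 0));
      Es.each_row() -= mu;
      for (arma::uword j = 0; j < Es.n_cols; ++j)
        if (sdev[j] > 0) Es.col(j) /= sdev[j];
    }
    const double d = arma::det(Es.t() * Es);
    trace[it] = d;
    if (d > best) {
      best = d;
      for (int i = 0; i < n; ++i) best_idx[i] = rows[i] + 1;
    }
    if (d < worst) {
      worst = d;
      for (int i = 0; i < n; ++i) worst_idx[i] = rows[i] + 1;
    }
  }
  return List::create(_["indices"] = best_idx, _["det"] = best,
                      _["worst_indices"] = worst_idx, _["worst_det"] = worst,
                      _["trace"] = trace);
}
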