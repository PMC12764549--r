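#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// Penalty of an m x d candidate: H*(#const cols + #const rows + #pairs
// |r| > hard) + #pairs soft < |r| <= hard, H = d^2 + 1.
double penalty_of(const arma::mat& vals, const double soft, const double hard,
                  int* zero_out, int* hard_out, int* soft_out) {
  const int d = vals.n_cols;
  const double H = static_cast<double>(d) * d + 1.0;
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
  if (zero_out) *zero_out = zero_var;
  if (hard_out) *hard_out = nhard;
  if (soft_out) *soft_out = nsoft;
  return H * (zero_var + nhard) + nsoft;
}

inline double draw_level(const int levels) {
  int v = static_cast<int>(unif_rand() * levels);
  if (v >= levels) v = levels - 1;
  return v;
}

// Penalty after replacing row `row` of `vals` with `cand`, evaluated
// incrementally from the cached cross-product matrix S = vals'vals and
// column sums s (O(d^2) per evaluation, no matrix rebuild).
double penalty_swapped(const arma::mat& vals, const arma::mat& S,
                       const arma::vec& s, const int row,
                       const arma::rowvec& cand, const int m,
                       const double soft, const double hard) {
  const int d = vals.n_cols;
  const double H = static_cast<double>(d) * d + 1.0;
  const arma::rowvec old = vals.row(row);
  const arma::vec s2 = s - old.t() + cand.t();
  // column variances * m
  arma::vec varm(d);
  for (int p = 0; p < d; ++p) {
    const double Spp = S(p, p) - old[p] * old[p] + cand[p] * cand[p];
    varm[p] = Spp - s2[p] * s2[p] / m;
  }
  int zero_var = 0;
  for (int p = 0; p < d; ++p) if (varm[p] <= 1e-9) ++zero_var;
  // row variances: only `row` changes
  const double cmu = arma::mean(cand);
  const double crv = arma::mean(arma::square(cand - cmu));
  if (crv <= 1e-12) ++zero_var;
  for (int i = 0; i < m; ++i) {
    if (i == row) continue;
    const arma::rowvec ri = vals.row(i);
    const double mu_i = arma::mean(ri);
    if (arma::mean(arma::square(ri - mu_i)) <= 1e-12) ++zero_var;
  }
  int nhard = 0, nsoft = 0;
  arma::vec isd(d);
  for (int p = 0; p < d; ++p)
    isd[p] = varm[p] > 1e-9 ? 1.0 / std::sqrt(varm[p]) : 0.0;
  const double soft2 = soft, hard2 = hard;
  for (int p = 0; p < d; ++p) {
    if (isd[p] == 0.0) continue;
    const double op = old[p], cp = cand[p], sp = s2[p];
    for (int q = p + 1; q < d; ++q) {
      if (isd[q] == 0.0) continue;
      const double Spq = S(p, q) - op * old[q] + cp * cand[q];
      const double covm = Spq - sp * s2[q] / m;
      const double r = std::fabs(covm) * isd[p] * isd[q];
      if (r > hard2) ++nhard;
      else if (r > soft2) ++nsoft;
    }
  }
  return H * (zero_var + nhard) + nsoft;
}

}  // namespace

// Incremental combination search for the mother-media simulation: start
// from a random m x d level matrix, then for each of `inner_iters`
// iterations draw one fresh random medium (a d-vector of levels) and test
// it in every row position; the replacement that most reduces the penalty
// (strictly, first row on ties) is applied. This selects a low-penalty
// combination of mother media from the stream of randomly generated ones.
// [[Rcpp::export]]
List swap_candidate_cpp(const int m, const int d, const int levels,
                        const int inner_iters, const double soft,
                        const double hard) {
  arma::mat vals(m, d);
  for (int j = 0; j < m * d; ++j) vals[j] = draw_level(levels);
  arma::mat S = vals.t() * vals;
  arma::vec s = arma::sum(vals, 0).t();
  int zv, nh, ns;
  double cur = penalty_of(vals, soft, hard, &zv, &nh, &ns);
  arma::rowvec cand(d);
  for (int it = 0; it < inner_iters; ++it) {
    for (int j = 0; j < d; ++j) cand[j] = draw_level(levels);
    double best = cur;
    int best_row = -1;
    for (int i = 0; i < m; ++i) {
      const double p = penalty_swapped(vals, S, s, i, cand, m, soft, hard);
      if (p < best) { best = p; best_row = i; }
    }
    if (best_row >= 0) {
      const arma::rowvec old = vals.row(best_row);
      S += cand.t() * cand - old.t() * old;
      s += cand.t() - old.t();
      vals.row(best_row) = cand;
      cur = best;
    }
  }
  cur = penalty_of(vals, soft, hard, &zv, &nh, &ns);
  return List::create(_["values"] = vals, _["zero_variance"] = zv,
                      _["hard_pairs"] = nh, _["soft_pairs"] = ns,
                      _["total"] = cur);
}
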