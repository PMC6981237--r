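// Hot loop for cross-validated linear discriminant accuracy.
// Same model as the R-level fit_lda()/predict(): class means, pooled
// within-class covariance with relative ridge eps*trace(S)/d on the
// diagonal, empirical priors, argmax of the linear discriminant score with
// ties broken toward the earlier class. Keeping the fold loop in C++ makes
// wrapper feature selection (thousands of small CV fits) tractable.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// scores: n x g matrix of discriminant scores -> predicted class indices
// (0-based), ties toward the lower class index
static uvec argmax_rows(const mat& scores) {
  uvec out(scores.n_rows);
  for (uword i = 0; i < scores.n_rows; ++i) {
    uword best = 0;
    double bv = scores(i, 0);
    for (uword k = 1; k < scores.n_cols; ++k)
      if (scores(i, k) > bv) { bv = scores(i, k); best = k; }
    out(i) = best;
  }
  return out;
}

// Fit LDA on (X, y) rows `train`, return predicted classes for rows `test`.
// y: 0-based class indices, g classes all present in train.
static uvec lda_fit_predict(const mat& X, const uvec& y, const uvec& train,
                            const uvec& test, uword g, double ridge_rel) {
  const uword d = X.n_cols;
  mat means(g, d, fill::zeros);
  vec counts(g, fill::zeros);
  for (uword idx = 0; idx < train.n_elem; ++idx) {
    uword i = train(idx);
    means.row(y(i)) += X.row(i);
    counts(y(i)) += 1.0;
  }
  for (uword k = 0; k < g; ++k) means.row(k) /= counts(k);

  mat S(d, d, fill::zeros);
  for (uword idx = 0; idx < train.n_elem; ++idx) {
    uword i = train(idx);
    rowvec c = X.row(i) - means.row(y(i));
    S += c.t() * c;
  }
  double denom = (double)train.n_elem - (double)g;
  if (denom < 1.0) denom = 1.0;
  S /= denom;
  if (ridge_rel > 0.0) {
    double eps = ridge_rel * trace(S) / (double)d;
    S.diag() += eps;
  }

  mat W = solve(S, means.t(), solve_opts::likely_sympd);  // d x g
  vec consts(g);
  for (uword k = 0; k < g; ++k)
    consts(k) = -0.5 * dot(means.row(k), W.col(k)) +
                std::log(counts(k) / (double)train.n_elem);

  mat scores = X.rows(test) * W;
  scores.each_row() += consts.t();
  return argmax_rows(scores);
}

// [[Rcpp::export(name = ".cv_lda_kernel")]]
Rcpp::NumericVector cv_lda_kernel(const arma::mat& X,
                                  const arma::ivec& y,
                                  const arma::imat& folds,
                                  int n_classes, int k_folds,
                                  double ridge_rel) {
  const uword n = X.n_rows;
  const uword R = folds.n_cols;
  uvec yy(n);
  for (uword i = 0; i < n; ++i) yy(i) = (uword)y(i);
  Rcpp::NumericVector out(R);
  for (uword r = 0; r < R; ++r) {
    double fold_acc_sum = 0.0;
    for (int f = 1; f <= k_folds; ++f) {
      std::vector<uword> tr, te;
      for (uword i = 0; i < n; ++i)
        (folds(i, r) == f ? te : tr).push_back(i);
      uvec train(tr), test(te);
      uvec pred = lda_fit_predict(X, yy, train, test, (uword)n_classes, ridge_rel);
      uword correct = 0;
      for (uword j = 0; j < test.n_elem; ++j)
        if (pred(j) == yy(test(j))) ++correct;
      fold_acc_sum += (double)correct / (double)test.n_elem;
    }
    out[r] = fold_acc_sum / (double)k_folds;
  }
  return out;
}
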