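// PLS1 (single-response partial least squares) kernels.
//
// NIPALS with X-deflation; coefficient paths for 1..A latent factors are
// accumulated through the R = W (P'W)^{-1} recursion so one decomposition
// yields the model for every factor count, which is what the
// cross-validated factor search and the BOSS sub-model loop need.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fills B (p x A) with centered-space coefficient vectors for 1..A factors.
// Returns the number of factors actually extracted; columns beyond that are
// padded with the last achieved coefficient vector (the model stops
// changing once the residual X carries no usable covariance with y).
static int pls1_path(const mat& X, const vec& y, const int A, mat& B,
                     const double tol) {
  const uword p = X.n_cols;
  rowvec xm = mean(X, 0);
  mat Xc = X.each_row() - xm;
  vec yc = y - mean(y);

  B.zeros(p, A);
  mat P(p, A, fill::none), R(p, A, fill::none);
  vec b(p, fill::zeros);

  int a = 0;
  for (; a < A; ++a) {
    vec w = Xc.t() * yc;
    const double wn = norm(w, 2);
    if (wn < tol) break;
    w /= wn;
    vec t = Xc * w;
    const double tt = dot(t, t);
    if (tt < tol * tol) break;
    vec pv = Xc.t() * t / tt;
    const double q = dot(yc, t) / tt;
    Xc -= t * pv.t();
    yc -= q * t;

    vec r = w;
    for (int j = 0; j < a; ++j) r -= dot(P.col(j), w) * R.col(j);
    P.col(a) = pv;
    R.col(a) = r;
    b += q * r;
    B.col(a) = b;
  }
  for (int j = a; j < A; ++j)
    B.col(j) = (a > 0) ? B.col(a - 1) : vec(p, fill::zeros);
  return a;
}

// [[Rcpp::export]]
Rcpp::List pls1_fit_cpp(const arma::mat& X, const arma::vec& y, int ncomp,
                        double tol = 1e-12) {
  mat B;
  const int used = pls1_path(X, y, ncomp, B, tol);
  return Rcpp::List::create(
      Rcpp::Named("coef_path") = B,
      Rcpp::Named("x_mean") = rowvec(mean(X, 0)),
      Rcpp::Named("y_mean") = mean(y),
      Rcpp::Named("ncomp_used") = used);
}

// Out-of-fold predictions for every factor count 1..ncomp.
// fold: 1-based fold id per sample. Returns an n x ncomp matrix.
// [[Rcpp::export]]
arma::mat pls1_cv_cpp(const arma::mat& X, const arma::vec& y, int ncomp,
                      const arma::ivec& fold, double tol = 1e-12) {
  const uword n = X.n_rows;
  const int k = fold.max();
  mat pred(n, ncomp, fill::zeros);

  for (int f = 1; f <= k; ++f) {
    const uvec test_idx = find(fold == f);
    const uvec train_idx = find(fold != f);
    if (test_idx.n_elem == 0) continue;

    const mat Xtr = X.rows(train_idx);
    const vec ytr = y.elem(train_idx);
    int a_max = std::min<int>(ncomp, std::min<uword>(Xtr.n_rows - 1, X.n_cols));
    if (a_max < 1) a_max = 1;

    mat B;
    pls1_path(Xtr, ytr, a_max, B, tol);
    const rowvec xm = mean(Xtr, 0);
    const double ym = mean(ytr);

    const mat Xte = X.rows(test_idx);
    mat Pte = (Xte.each_row() - xm) * B;
    Pte += ym;
    // pad factor counts this fold could not reach
    mat Pfull(test_idx.n_elem, ncomp);
    for (int a = 0; a < ncomp; ++a)
      Pfull.col(a) = Pte.col(std::min(a, a_max - 1));
    pred.rows(test_idx) = Pfull;
  }
  return pred;
}
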