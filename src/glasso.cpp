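// Sparse inverse-correlation estimation: graphical lasso by block coordinate
// descent (Friedman-Hastie-Tibshirani scheme) with warm-started penalty paths.
// Kept in C++ because the resampling diagnostics re-estimate the model tens of
// thousands of times.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Coordinate-descent lasso for one block subproblem:
//   min_beta 1/2 beta' W11 beta - beta' s12 + lambda ||beta||_1
static void lasso_cd(const arma::mat& W11, const arma::vec& s12, double lambda,
                     arma::vec& beta, double tol, int maxit) {
  const int p = s12.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double dlx = 0.0;
    for (int k = 0; k < p; ++k) {
      double bk = beta(k);
      // partial residual: s12_k - sum_{l != k} W11_kl beta_l
      double grad = s12(k) - arma::dot(W11.col(k), beta) + W11(k, k) * bk;
      double bnew = 0.0;
      if (grad > lambda) bnew = (grad - lambda) / W11(k, k);
      else if (grad < -lambda) bnew = (grad + lambda) / W11(k, k);
      if (bnew != bk) {
        beta(k) = bnew;
        double d = std::fabs(bnew - bk);
        if (d > dlx) dlx = d;
      }
    }
    if (dlx < tol) break;
  }
}

// One glasso solve at a single penalty. W is modified in place (warm start).
// Returns the precision matrix Theta; `edges` gets the exact-zero pattern
// derived from the lasso coefficients (AND rule across the two directions).
static arma::mat glasso_solve(const arma::mat& S, double lambda,
                              bool penalize_diagonal, double tol, int maxit,
                              arma::mat& W, arma::mat& Beta, bool& converged) {
  const int p = S.n_rows;
  converged = true;
  if (lambda <= 0.0) {
    arma::mat Theta = arma::inv_sympd(S);
    W = S;
    // dense solution: all coefficients active
    Beta.fill(1.0);
    Beta.diag().zeros();
    return Theta;
  }
  // diagonal of W fixed throughout the iterations
  for (int j = 0; j < p; ++j)
    W(j, j) = S(j, j) + (penalize_diagonal ? lambda : 0.0);

  const double thr = tol * arma::mean(arma::mean(arma::abs(
      S - arma::diagmat(S.diag()))));
  const double eps = (thr > 0) ? thr : tol;
  // inner solves must settle below the sweep threshold or the outer
  // loop chases coefficient noise forever
  const double eps_inner = 0.1 * eps;

  arma::uvec idx(p - 1);
  converged = false;
  for (int sweep = 0; sweep < maxit; ++sweep) {
    double dw = 0.0;
    for (int j = 0; j < p; ++j) {
      int m = 0;
      for (int k = 0; k < p; ++k) if (k != j) idx(m++) = k;
      arma::mat W11 = W.submat(idx, idx);
      arma::vec s12 = S.col(j);
      s12 = s12.elem(idx);
      arma::vec beta = Beta.col(j);
      beta = beta.elem(idx);
      lasso_cd(W11, s12, lambda, beta, eps_inner, maxit);
      arma::vec w12 = W11 * beta;
      for (int k = 0; k < p - 1; ++k) {
        double d = std::fabs(W(idx(k), j) - w12(k));
        if (d > dw) dw = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        Beta(idx(k), j) = beta(k);
      }
    }
    if (dw < eps) { converged = true; break; }
  }

  // back out Theta column-wise from the final coefficients
  arma::mat Theta(p, p, arma::fill::zeros);
  for (int j = 0; j < p; ++j) {
    int m = 0;
    for (int k = 0; k < p; ++k) if (k != j) idx(m++) = k;
    arma::vec beta = Beta.col(j);
    beta = beta.elem(idx);
    arma::vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double tjj = 1.0 / (W(j, j) - arma::dot(w12, beta));
    Theta(j, j) = tjj;
    for (int k = 0; k < p - 1; ++k) Theta(idx(k), j) = -beta(k) * tjj;
  }
  // symmetrise; an entry is an edge only if both directions kept it active
  arma::mat Th = 0.5 * (Theta + Theta.t());
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < p; ++i)
      if (i != j && (Beta(i, j) == 0.0 || Beta(j, i) == 0.0)) Th(i, j) = 0.0;
  return 0.5 * (Th + Th.t());
}

// [[Rcpp::export(name = ".glasso_cpp")]]
List glasso_cpp(const arma::mat& S, double lambda, bool penalize_diagonal,
                double tol, int maxit) {
  const int p = S.n_rows;
  arma::mat W = S, Beta(p, p, arma::fill::zeros);
  bool conv = true;
  arma::mat Theta = glasso_solve(S, lambda, penalize_diagonal, tol, maxit,
                                 W, Beta, conv);
  return List::create(_["theta"] = Theta, _["w"] = W, _["converged"] = conv);
}

// Warm-started descent along a (descending) penalty path. Returns the list of
// precision matrices plus per-lambda log-likelihood terms and edge counts so
// the information-criterion scan stays out of the R loop.
// [[Rcpp::export(name = ".glasso_path_cpp")]]
List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                     bool penalize_diagonal, double tol, int maxit) {
  const int p = S.n_rows;
  const int L = lambdas.n_elem;
  arma::mat W = S, Beta(p, p, arma::fill::zeros);
  List thetas(L);
  arma::vec loglik_term(L), nedges(L);
  LogicalVector conv(L);
  for (int l = 0; l < L; ++l) {
    bool ok = true;
    arma::mat Theta = glasso_solve(S, lambdas(l), penalize_diagonal, tol,
                                   maxit, W, Beta, ok);
    conv(l) = ok;
    double sign, ld;
    arma::log_det(ld, sign, Theta);
    loglik_term(l) = ld - arma::trace(S * Theta);
    int E = 0;
    for (int j = 1; j < p; ++j)
      for (int i = 0; i < j; ++i)
        if (Theta(i, j) != 0.0) ++E;
    nedges(l) = E;
    thetas[l] = Theta;
  }
  return List::create(_["theta"] = thetas, _["loglik_term"] = loglik_term,
                      _["nedges"] = nedges, _["converged"] = conv);
}
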