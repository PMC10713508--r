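#' Graphical lasso at a single penalty
#'
#' L1-penalised Gaussian maximum likelihood for a sparse precision matrix:
#' maximises \eqn{\log\det\Theta - \mathrm{tr}(S\Theta) -
#' \lambda\sum_{i \ne j}|\theta_{ij}|} by block coordinate descent. The
#' diagonal is unpenalised by default, so `lambda = 0` returns the exact
#' unpenalised MLE \eqn{S^{-1}}.
#'
#' @param S An [correlation_matrix()] result or symmetric positive definite
#'   matrix.
#' @param lambda Penalty, `>= 0`.
#' @param penalize_diagonal Also penalise the diagonal (default `FALSE`).
#' @param tol Convergence tolerance (relative to mean absolute
#'   off-diagonal of `S`).
#' @param maxit Maximum sweeps.
#' @return The precision matrix with attributes `objective` (the penalised
#'   negative log-likelihood value being minimised) and `converged`.
#' @export
glasso_fit <- function(S, lambda, penalize_diagonal = FALSE, tol = 1e-6,
                       maxit = 10000) {
  Sm <- if (inherits(S, "shs_cor")) S$values else as.matrix(S)
  stopifnot(lambda >= 0)
  if (min(eigen(Sm, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("S is not positive definite; repair it with nearest_pd()",
         call. = FALSE)
  fit <- .glasso_cpp(Sm, lambda, penalize_diagonal, tol, maxit)
  if (!fit$converged)
    stop("graphical lasso did not converge in ", maxit, " sweeps",
         call. = FALSE)
  theta <- fit$theta
  dimnames(theta) <- dimnames(Sm)
  off <- theta; diag(off) <- 0
  attr(theta, "objective") <- -determinant(theta)$modulus[1] +
    sum(Sm * theta) + lambda * sum(abs(off))
  attr(theta, "converged") <- fit$converged
  theta
}

#' Penalty path for EBIC model selection
#'
#' `n_lambdas` log-spaced values descending from \eqn{\lambda_{max}} (the
#' largest absolute off-diagonal of `S`, at which the model is empty) down
#' to \eqn{\lambda_{max} \times} `lambda_min_ratio`.
#'
#' @inheritParams glasso_fit
#' @param n_lambdas Path length (default 100).
#' @param lambda_min_ratio Ratio of smallest to largest penalty
#'   (default 0.01).
#' @return Numeric vector of penalties, descending.
#' @export
lambda_path <- function(S, n_lambdas = 100, lambda_min_ratio = 0.01) {
  Sm <- if (inherits(S, "shs_cor")) S$values else as.matrix(S)
  stopifnot(n_lambdas >= 2, lambda_min_ratio > 0, lambda_min_ratio < 1)
  lmax <- max(abs(Sm[row(Sm) != col(Sm)]))
  if (lmax == 0) {
    warning("all off-diagonal correlations are zero; single-point path {0}",
            call. = FALSE)
    return(0)
  }
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambdas))
}

#' Extended Bayesian Information Criterion of a fitted precision matrix
#'
#' \deqn{\mathrm{EBIC}_\gamma = -2\ell + E\log n + 4\gamma E\log p,}
#' with \eqn{\ell = (n/2)(\log\det\Theta - \mathrm{tr}(S\Theta))} (additive
#' constants dropped) and \eqn{E} the number of nonzero off-diagonal pairs.
#' `gamma = 0` recovers the ordinary BIC structure; larger `gamma`
#' penalises model-space size, favouring sparser graphs.
#'
#' @param theta Precision matrix (positive definite).
#' @param S Correlation matrix the model was fitted to.
#' @param n Sample size.
#' @param gamma EBIC hyperparameter, `>= 0` (default 0.5).
#' @return The criterion value (smaller is better).
#' @export
ebic_score <- function(theta, S, n, gamma = 0.5) {
  Sm <- if (inherits(S, "shs_cor")) S$values else as.matrix(S)
  stopifnot(gamma >= 0, n > 0)
  ld <- determinant(theta)$modulus[1]
  if (!is.finite(ld))
    stop("theta must be positive definite for the log-determinant",
         call. = FALSE)
  p <- ncol(theta)
  E <- sum(theta[upper.tri(theta)] != 0)
  ll <- (n / 2) * (ld - sum(Sm * theta))
  -2 * ll + E * log(n) + 4 * gamma * E * log(p)
}
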