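S2 <- matrix(c(1, 0.5, 0.5, 1), 2)

test_that("the unpenalised fit is the inverse correlation matrix", {
  set.seed(41)
  A <- matrix(rnorm(25), 5)
  S <- stats::cov2cor(crossprod(A) + diag(5))
  theta <- glasso_fit(S, lambda = 0)
  expect_lt(max(abs(theta - solve(S))), 1e-6)
})

test_that("penalties at or above the largest off-diagonal empty the graph", {
  theta <- glasso_fit(S2, lambda = 0.5)
  expect_equal(theta[1, 2], 0)
  theta <- glasso_fit(S2, lambda = 0.9)
  expect_equal(sum(theta != 0), 2)
})

test_that("the bivariate solution soft-thresholds the correlation", {
  theta <- glasso_fit(S2, lambda = 0.2)
  pcor <- -theta[1, 2] / sqrt(theta[1, 1] * theta[2, 2])
  expect_equal(pcor, 0.3, tolerance = 1e-6)
})

test_that("the solver matches a brute-force numeric optimiser for p = 2, 3", {
  set.seed(42)
  mats <- list(S2, matrix(c(1, -0.35, -0.35, 1), 2))
  A <- matrix(rnorm(9), 3)
  mats$S3a <- stats::cov2cor(crossprod(A) + diag(3))
  B <- matrix(rnorm(9), 3)
  mats$S3b <- stats::cov2cor(crossprod(B) + 2 * diag(3))
  worst <- 0
  for (S in mats) for (lam in c(0.02, 0.05, 0.1, 0.2, 0.4)) {
    fit <- glasso_fit(S, lam, tol = 1e-9, maxit = 5000)
    oracle <- glasso_numeric_oracle(S, lam, start = unclass(fit))
    # the solver may never do worse than the oracle on the objective
    expect_lte(penalised_objective(unclass(fit), S, lam),
               penalised_objective(oracle, S, lam) + 1e-8)
    worst <- max(worst, max(abs(fit - oracle)))
  }
  expect_lt(worst, 1e-4)
})

test_that("lambda path is log-spaced from the largest off-diagonal", {
  path <- lambda_path(S2, n_lambdas = 25, lambda_min_ratio = 0.01)
  expect_equal(length(path), 25)
  expect_equal(path[1], 0.5)
  expect_equal(path[25], 0.005)
  expect_true(all(diff(path) < 0))
  expect_warning(p0 <- lambda_path(diag(3)), "zero")
  expect_equal(p0, 0)
})

test_that("EBIC matches the hand formula and its gamma term", {
  theta <- diag(3)
  theta[1, 2] <- theta[2, 1] <- -0.2
  theta[2, 3] <- theta[3, 2] <- -0.15   # E = 2 edges
  S <- stats::cov2cor(solve(theta))
  n <- 100
  ll <- (n / 2) * (determinant(theta)$modulus[1] - sum(S * theta))
  expect_equal(ebic_score(theta, S, n, gamma = 0.5),
               -2 * ll + 2 * log(100) + 4 * 0.5 * 2 * log(3))
  expect_equal(ebic_score(theta, S, n, gamma = 0.5) -
                 ebic_score(theta, S, n, gamma = 0),
               4 * 0.5 * 2 * log(3))
})

test_that("a zero-weight edge cannot decrease the EBIC", {
  theta <- diag(2)
  S <- S2
  e0 <- ebic_score(theta, S, 50)
  theta_eps <- theta
  theta_eps[1, 2] <- theta_eps[2, 1] <- 1e-9  # counted as an edge
  expect_gt(ebic_score(theta_eps, S, 50), e0)
})

test_that("an identity correlation matrix yields an empty network", {
  net <- suppressWarnings(estimate_network(structure(list(values = diag(4),
                                         labels = paste0("V", 1:4),
                                         method = "pearson",
                                         n_effective = 100,
                                         pd_repaired = FALSE),
                                    class = "shs_cor"), n = 100))
  expect_equal(network_summary(net)$edge_count, 0)
})

test_that("bivariate selection agrees with exhaustive two-model
           enumeration", {
  for (r in c(0.2, 0.5, 0.7)) for (n in c(30, 100, 500)) {
    S <- matrix(c(1, r, r, 1), 2)
    Sc <- structure(list(values = S, labels = c("A", "B"),
                         method = "pearson", n_effective = n,
                         pd_repaired = FALSE), class = "shs_cor")
    net <- suppressWarnings(estimate_network(Sc, n = n))
    # the only candidate models: independence vs the dense MLE
    e_empty <- ebic_score(diag(2), S, n, gamma = 0.5)
    e_dense <- ebic_score(solve(S), S, n, gamma = 0.5)
    has_edge <- network_summary(net)$edge_count == 1
    expect_equal(has_edge, e_dense < e_empty,
                 info = sprintf("r=%.1f n=%d", r, n))
  }
})

test_that("edge count is monotone non-increasing along the penalty path", {
  set.seed(43)
  tr <- shs_truth(p = 8, density = 0.3, seed = 44)
  pre <- cohort_preset("custom", n = 400, mean = rep(1.5, 8), sd = rep(1, 8))
  co <- generate_cohort(tr, pre, seed = 45)
  net <- shs_network(co$ratings, method = "spearman", n_lambdas = 40)
  expect_true(all(diff(net$path$edges) >= 0))  # path is descending in lambda
})

test_that("partial correlations at lambda = 0 equal the classical values
           and re-fitting is bit-identical", {
  set.seed(46)
  A <- matrix(rnorm(16), 4)
  S <- stats::cov2cor(crossprod(A) + diag(4))
  theta <- glasso_fit(S, 0)
  pcor <- -stats::cov2cor(unclass(theta))
  diag(pcor) <- 0
  ref <- -stats::cov2cor(solve(S))
  diag(ref) <- 0
  expect_equal(pcor, ref, tolerance = 1e-10, ignore_attr = TRUE)

  tr <- shs_truth(p = 6, density = 0.3, seed = 47)
  pre <- cohort_preset("custom", n = 200, mean = rep(1.4, 6), sd = rep(1, 6))
  co <- generate_cohort(tr, pre, seed = 48)
  n1 <- shs_network(co$ratings, method = "spearman")
  n2 <- shs_network(co$ratings, method = "spearman")
  expect_identical(n1$weights, n2$weights)
  expect_identical(n1$lambda, n2$lambda)
})

test_that("network summaries report density and mean edge weight", {
  w <- matrix(0, 25, 25)
  w[upper.tri(w)][1:58] <- c(rep(0.05, 29), rep(-0.03, 29))
  w <- w + t(w)
  s <- network_summary(w)
  expect_equal(s$edge_count, 58)
  expect_equal(s$possible_edges, 300)
  expect_equal(round(s$density, 3), 0.193)
  expect_equal(s$mean_abs_nonzero_weight, 0.04)
  expect_equal(network_summary(w, weight_mean = "signed_nonzero")$
                 mean_abs_nonzero_weight, mean(c(rep(0.05, 29),
                                                 rep(-0.03, 29))))
  e <- network_summary(matrix(0, 5, 5))
  expect_true(e$empty)
  expect_equal(e$density, 0)
  expect_equal(e$mean_abs_nonzero_weight, 0)
})
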