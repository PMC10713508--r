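chain3 <- function() {
  w <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  w["A", "B"] <- w["B", "A"] <- 0.5
  w["B", "C"] <- w["C", "B"] <- 0.25
  w
}

test_that("centralities of a 3-node chain match hand computation", {
  cent <- centrality_indices(chain3())
  expect_equal(cent$strength, c(0.5, 0.75, 0.25))
  # distances: d(A,B) = 2, d(B,C) = 4, d(A,C) = 6
  expect_equal(cent$closeness, c(1 / 8, 1 / 6, 1 / 10))
  expect_equal(cent$betweenness, c(0, 1, 0))
})

test_that("the centre of a symmetric star dominates all three indices", {
  w <- matrix(0, 4, 4)
  w[1, 2:4] <- w[2:4, 1] <- 0.3
  cent <- centrality_indices(w)
  expect_true(all(cent$strength[1] > cent$strength[2:4]))
  expect_true(all(cent$closeness[1] > cent$closeness[2:4]))
  expect_true(all(cent$betweenness[1] > cent$betweenness[2:4]))
  expect_equal(length(unique(round(cent$strength[2:4], 12))), 1)
})

test_that("rescaling weights scales strength, rescales closeness and leaves
           betweenness fixed", {
  w <- chain3()
  c1 <- centrality_indices(w)
  c2 <- centrality_indices(2 * w)
  expect_equal(c2$strength, 2 * c1$strength)
  expect_equal(c2$closeness, 2 * c1$closeness)  # all distances halve
  expect_equal(c2$betweenness, c1$betweenness)
})

test_that("centralities are equivariant under node permutation", {
  set.seed(51)
  tr <- shs_truth(p = 7, density = 0.4, seed = 52)
  w <- tr$pcor
  cent <- centrality_indices(w)
  perm <- sample(7)
  cent_p <- centrality_indices(w[perm, perm])
  expect_equal(cent_p$strength, cent$strength[perm])
  expect_equal(cent_p$closeness, cent$closeness[perm])
  expect_equal(cent_p$betweenness, cent$betweenness[perm])
})

test_that("weighted betweenness matches exhaustive path enumeration on
           small graphs", {
  set.seed(53)
  for (rep in 1:5) {
    p <- sample(5:7, 1)
    w <- matrix(0, p, p)
    pairs <- which(upper.tri(w))
    on <- sample(pairs, size = round(0.5 * length(pairs)))
    w[on] <- sample(c(0.2, 0.4, 0.8), length(on), replace = TRUE)
    w <- w + t(w)
    cent <- centrality_indices(w)
    expect_equal(cent$betweenness, brute_betweenness(w), tolerance = 1e-10)
  }
})

test_that("an empty network yields zero centralities with a warning", {
  expect_warning(cent <- centrality_indices(matrix(0, 4, 4)), "empty")
  expect_true(all(cent$strength == 0 & cent$closeness == 0 &
                    cent$betweenness == 0))
})

test_that("z-scores standardise each index across nodes", {
  set.seed(54)
  tr <- shs_truth(p = 9, density = 0.35, seed = 55)
  cent <- centrality_indices(tr$pcor)
  for (col in c("strength_z", "closeness_z", "betweenness_z")) {
    expect_equal(mean(cent[[col]]), 0, tolerance = 1e-12)
    expect_equal(stats::sd(cent[[col]]), 1, tolerance = 1e-12)
  }
  expect_equal(dim(attr(cent, "index_correlations")), c(3L, 3L))
})

test_that("bivariate predictability equals the squared partial
           correlation", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  net <- net_from_theta(glasso_fit(S, 0))
  pred <- node_predictability(net)
  expect_equal(pred$predictability, c(0.25, 0.25), tolerance = 1e-10)
})

test_that("an empty network has zero predictability everywhere", {
  net <- net_from_theta(diag(3))
  pred <- node_predictability(net)
  expect_equal(pred$predictability, c(0, 0, 0))
})

test_that("unpenalised predictability equals nodewise regression R^2", {
  set.seed(56)
  tr <- shs_truth(p = 6, density = 0.4, seed = 57)
  X <- MASS::mvrnorm(300, rep(0, 6), tr$sigma)
  S <- stats::cor(X)
  net <- net_from_theta(glasso_fit(S, 0))
  pred <- node_predictability(net)
  Xs <- scale(X)
  for (j in 1:6) {
    fit <- stats::lm(Xs[, j] ~ Xs[, -j])
    expect_equal(pred$predictability[j], summary(fit)$r.squared,
                 tolerance = 1e-6)
  }
})

test_that("adding a truly correlated neighbour cannot reduce unpenalised
           predictability", {
  set.seed(58)
  K <- diag(3)
  K[1, 2] <- K[2, 1] <- -0.4
  K[1, 3] <- K[3, 1] <- -0.3
  sigma <- stats::cov2cor(solve(K))
  X <- MASS::mvrnorm(500, rep(0, 3), sigma)
  S3 <- stats::cor(X)
  pred3 <- node_predictability(net_from_theta(glasso_fit(S3, 0)))
  S2 <- S3[1:2, 1:2]
  pred2 <- node_predictability(net_from_theta(glasso_fit(S2, 0)))
  expect_gte(pred3$predictability[1] + 1e-12, pred2$predictability[1])
})

test_that("the refit variant agrees broadly with the analytic definition", {
  set.seed(59)
  tr <- shs_truth(p = 8, density = 0.3, seed = 60)
  pre <- cohort_preset("custom", n = 800, mean = rep(1.5, 8), sd = rep(1, 8))
  co <- generate_cohort(tr, pre, seed = 61)
  net <- shs_network(co$ratings, method = "spearman", n_lambdas = 30)
  a <- node_predictability(net)
  b <- node_predictability(net, method = "refit", data = co)
  expect_equal(stats::cor(a$predictability, b$predictability) > 0.8, TRUE)
})

test_that("mean predictability reproduces the published domain averages", {
  expect_equal(as.numeric(predictability_summary(
    c(0.61, 0.78, 0.67, 0.56, 0.48))), 0.62)
  expect_equal(as.numeric(predictability_summary(
    c(0.81, 0.68, 0.74, 0.64, 0.39))), 0.65)
  expect_equal(as.numeric(predictability_summary(rep(0, 4))), 0)
})
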