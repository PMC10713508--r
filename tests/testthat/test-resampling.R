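test_that("bootstrap quantile intervals bracket the point estimates", {
  co <- make_cohort()
  boot <- bootstrap_edges(co, B = 120, seed = 72, method = "spearman",
                          n_lambdas = 20)
  covered <- with(boot$cis, estimate >= lower & estimate <= upper)
  expect_gt(mean(covered), 0.9)
  expect_equal(boot$n_dropped, 0)
})

test_that("B = 1 collapses the interval to a point", {
  co <- make_cohort(n = 120)
  expect_warning(boot <- bootstrap_edges(co, B = 1, seed = 73,
                                         method = "spearman",
                                         n_lambdas = 15), "B < 100")
  expect_equal(boot$cis$lower, boot$cis$upper)
})

test_that("a fixed seed reproduces the ensemble exactly", {
  co <- make_cohort(n = 100)
  b1 <- suppressWarnings(bootstrap_edges(co, B = 25, seed = 74,
                                         method = "spearman",
                                         n_lambdas = 15))
  b2 <- suppressWarnings(bootstrap_edges(co, B = 25, seed = 74,
                                         method = "spearman",
                                         n_lambdas = 15))
  expect_identical(b1$edge_weights, b2$edge_weights)
})

test_that("difference tests never flag an edge against itself or ties", {
  co <- make_cohort()
  boot <- suppressWarnings(bootstrap_edges(co, B = 60, seed = 75,
                                           method = "spearman",
                                           n_lambdas = 15))
  D <- difference_tests(boot)
  expect_true(all(diag(D) == FALSE))
  expect_true(isSymmetric(unclass(D)))
  # force two identical replicate columns: never "different"
  boot$edge_weights[, 2] <- boot$edge_weights[, 1]
  D2 <- difference_tests(boot)
  expect_false(D2[1, 2])
})

test_that("a strong edge is distinguished from an absent one", {
  K <- diag(4)
  K[1, 2] <- K[2, 1] <- -0.55   # strong true edge 1-2; pair 3-4 empty
  K[2, 3] <- K[3, 2] <- -0.2
  sigma <- stats::cov2cor(solve(K))
  set.seed(76)
  X <- MASS::mvrnorm(1000, rep(0, 4), sigma)
  colnames(X) <- paste0("V", 1:4)
  boot <- bootstrap_edges(X, B = 120, seed = 77, method = "pearson",
                          n_lambdas = 20)
  D <- difference_tests(boot)
  strong <- "V1--V2"
  absent <- "V3--V4"
  expect_true(D[strong, absent])
})

test_that("zero case-dropping reproduces the original centralities
           exactly", {
  co <- make_cohort(n = 120)
  stab <- case_drop_stability(co, proportions = c(0, 0.2), B_per_level = 5,
                              seed = 78, method = "spearman",
                              n_lambdas = 15)
  at0 <- stab$curves[stab$curves$proportion == 0 &
                       stab$curves$index == "strength", "correlation"]
  expect_equal(at0, rep(1, 5))
})

test_that("drop-curves decline stochastically with the drop fraction and
           are seed-reproducible", {
  co <- make_cohort(n = 250, density = 0.4)
  stab <- case_drop_stability(co, proportions = c(0.1, 0.75),
                              B_per_level = 25, seed = 79,
                              method = "spearman", n_lambdas = 15)
  med <- tapply(stab$curves$correlation[stab$curves$index == "strength"],
                stab$curves$proportion[stab$curves$index == "strength"],
                stats::median, na.rm = TRUE)
  expect_lte(med[["0.75"]], med[["0.1"]])
  stab2 <- case_drop_stability(co, proportions = c(0.1, 0.75),
                               B_per_level = 25, seed = 79,
                               method = "spearman", n_lambdas = 15)
  expect_identical(stab$curves, stab2$curves)
})

test_that("the drop grid is truncated to keep enough respondents", {
  co <- make_cohort(n = 40)
  expect_warning(stab <- case_drop_stability(co,
                                             proportions = c(0.1, 0.9),
                                             B_per_level = 3, seed = 80,
                                             method = "spearman",
                                             n_lambdas = 15),
                 "truncat")
  expect_equal(stab$proportions, 0.1)
  expect_error(suppressWarnings(
    case_drop_stability(co, proportions = 0.95, B_per_level = 3,
                        method = "spearman")), "empty")
})

test_that("the CS-coefficient applies its definition to known curves", {
  expect_equal(unname(cs_coefficient(fake_stability(
    list(`0.1` = 1, `0.3` = 1, `0.5` = 1, `0.75` = 1)))), 0.75)
  hand <- fake_stability(list(`0.1` = 0.95, `0.2` = 0.90, `0.3` = 0.80,
                              `0.4` = 0.72, `0.5` = 0.65))
  expect_equal(unname(cs_coefficient(hand)), 0.4)
  expect_equal(unname(cs_coefficient(fake_stability(
    list(`0.1` = 0.5, `0.3` = 0.4)))), 0)
})

test_that("CS is monotone in the threshold and the certainty level", {
  set.seed(81)
  qs <- seq(0.05, 0.75, by = 0.05)
  curve <- lapply(qs, function(q) 1 - q + stats::rnorm(40, 0, 0.05))
  names(curve) <- qs
  stab <- fake_stability(curve)
  cs1 <- cs_coefficient(stab, corr_threshold = 0.5)
  cs2 <- cs_coefficient(stab, corr_threshold = 0.7)
  cs3 <- cs_coefficient(stab, corr_threshold = 0.9)
  expect_true(cs1 >= cs2 && cs2 >= cs3)
  cc1 <- cs_coefficient(stab, certainty = 0.8)
  cc2 <- cs_coefficient(stab, certainty = 0.99)
  expect_gte(cc1, cc2)
})
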