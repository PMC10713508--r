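items25 <- shsq25_items()$item

test_that("total and domain scores follow the summation rule", {
  r <- matrix(0L, 3, 25, dimnames = list(NULL, items25))
  r[2, ] <- 4L
  r[3, startsWith(items25, "FT")] <- 2L
  sc <- shs_scores(likert_matrix(r))
  expect_equal(sc$total, c(0, 100, 18))
  expect_equal(unlist(sc[2, c("CS", "DS", "FT", "IS", "MH")],
                      use.names = FALSE), c(12, 12, 36, 12, 28))
  expect_equal(sc$FT[3], 18)
  expect_equal(sc$CS[3], 0)
})

test_that("domain scores always sum to the total and scoring is
           permutation-equivariant", {
  r <- make_ratings25(n = 12, seed = 5)
  sc <- shs_scores(likert_matrix(r))
  expect_equal(rowSums(sc[, c("CS", "DS", "FT", "IS", "MH")]), sc$total)
  perm <- sample(12)
  sc_p <- shs_scores(likert_matrix(r[perm, ]))
  expect_equal(sc_p$total, sc$total[perm])
})

test_that("median split labels strictly-above as suboptimal with ties to
           the configured side", {
  mk <- function(totals) {
    r <- matrix(0L, length(totals), 25, dimnames = list(NULL, items25))
    for (i in seq_along(totals)) {  # spread each total greedily over items
      left <- totals[i]
      for (j in seq_len(25)) {
        r[i, j] <- min(left, 4L)
        left <- left - r[i, j]
      }
    }
    shs_scores(likert_matrix(r))
  }
  s1 <- median_split(mk(c(10, 20, 30, 40)))
  expect_equal(as.character(s1$status),
               c("optimal", "optimal", "suboptimal", "suboptimal"))
  expect_equal(attr(s1, "median_cutoff"), 25)

  s2 <- median_split(mk(c(10, 20, 20, 40)))
  expect_equal(as.character(s2$status),
               c("optimal", "optimal", "optimal", "suboptimal"))
  s2b <- median_split(mk(c(10, 20, 20, 40)), ties = "suboptimal")
  expect_equal(as.character(s2b$status),
               c("optimal", "suboptimal", "suboptimal", "suboptimal"))

  expect_warning(s3 <- median_split(mk(c(7, 7, 7))), "degenerate")
  expect_true(all(s3$status == "optimal"))
})

test_that("Cohen's d recomputes the published effect sizes from summaries", {
  expect_equal(round(as.numeric(cohens_d(53.09, 7.57, 106,
                                         57.02, 10.43, 111)), 2), 0.43)
  expect_equal(round(as.numeric(cohens_d(142.06, 22.86, 106,
                                         149.70, 25.31, 111)), 2), 0.32)
  expect_equal(as.numeric(cohens_d(5, 1, 10, 5, 3, 12)), 0)
})

test_that("Cohen's d is symmetric under group swap and scale invariant", {
  set.seed(2)
  for (i in 1:20) {
    m1 <- runif(1, 0, 10); m2 <- runif(1, 0, 10)
    s1 <- runif(1, 0.5, 3); s2 <- runif(1, 0.5, 3)
    n1 <- sample(5:50, 1); n2 <- sample(5:50, 1)
    d12 <- as.numeric(cohens_d(m1, s1, n1, m2, s2, n2))
    expect_equal(d12, as.numeric(cohens_d(m2, s2, n2, m1, s1, n1)))
    k <- runif(1, 0.1, 7)
    expect_equal(d12, as.numeric(cohens_d(k * m1, k * s1, n1,
                                          k * m2, k * s2, n2)))
  }
  expect_error(cohens_d(1, 0, 5, 2, 0, 5), "undefined")
})

test_that("effect labels follow the standard magnitude bands", {
  expect_equal(as.character(effect_label(c(0.1, 0.2, 0.43, 0.5, 0.8, 1.2))),
               c("negligible", "small", "small", "medium", "large", "large"))
})

test_that("pooled t-test from summaries reproduces the published age
           comparison", {
  gc <- compare_groups_from_summaries(53.09, 7.57, 106, 57.02, 10.43, 111)
  expect_equal(gc$df, 215)
  expect_equal(round(gc$statistic, 2), 3.16)
  expect_equal(round(gc$p_value, 3), 0.002)
  expect_equal(round(gc$cohens_d, 2), 0.43)
  expect_equal(gc$effect_label, "small")  # 0.43 sits in the standard small band
})

test_that("categorical covariates get a chi-square test matching the
           hand-computed statistic", {
  # reconstruct respondent-level data from the published gender table
  counts <- c(opt_f = 59, opt_m = 47, sub_f = 74, sub_m = 37)
  status <- rep(c("optimal", "optimal", "suboptimal", "suboptimal"), counts)
  gender <- rep(c("F", "M", "F", "M"), counts)
  n <- length(status)
  r <- make_ratings25(n = n, seed = 3)
  m <- likert_matrix(r, covariates = data.frame(gender = factor(gender)))
  gc <- compare_groups(m, "gender", status = status)

  O <- table(factor(status), factor(gender))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(gc$statistic, sum((O - E)^2 / E))  # 2.77
  expect_equal(round(gc$statistic, 2), 2.77)
  expect_equal(round(gc$p_value, 2), 0.10)
})

test_that("identical group distributions give d = 0 and p = 1", {
  x <- rep(c(1, 2, 3, 4), 10)
  status <- rep(c("optimal", "suboptimal"), each = 20)
  r <- make_ratings25(n = 40, seed = 4)
  m <- likert_matrix(r, covariates = data.frame(v = c(x[1:20], x[1:20])))
  gc <- compare_groups(m, "v", status = status)
  expect_equal(gc$cohens_d, 0)
  expect_equal(gc$p_value, 1)
})
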