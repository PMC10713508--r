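#' Total and domain SHSQ-25 scores
#'
#' The total suboptimal-health score of a respondent is the sum of the 25
#' item ratings (range 0--100 for the canonical instrument); domain scores
#' sum the component subscale items, so the domain scores always add up to
#' the total.
#'
#' @param m A [likert_matrix()].
#' @param missing `"strict"` (default) refuses to score respondents with
#'   missing ratings; `"lenient"` drops them with a warning. No imputation.
#' @return A data frame of class `shs_scores` with one row per scored
#'   respondent: `respondent`, one column per domain, and `total`.
#' @export
#' @examples
#' m <- likert_matrix(matrix(2L, 2, 25,
#'   dimnames = list(NULL, shsq25_items()$item)))
#' shs_scores(m)
shs_scores <- function(m, missing = c("strict", "lenient")) {
  stopifnot(inherits(m, "likert_matrix"))
  missing <- match.arg(missing)
  incomplete <- rowSums(is.na(m$ratings)) > 0
  if (any(incomplete)) {
    who <- paste(m$respondent_ids[incomplete], collapse = ", ")
    if (missing == "strict")
      stop("missing ratings for respondent(s): ", who,
           " (use missing = \"lenient\" to drop them)", call. = FALSE)
    warning("dropping ", sum(incomplete),
            " respondent(s) with missing ratings: ", who, call. = FALSE)
  }
  r <- m$ratings[!incomplete, , drop = FALSE]
  domains <- unique(m$domain_map)
  ds <- sapply(domains, function(d)
    rowSums(r[, m$domain_map == d, drop = FALSE]))
  if (nrow(r) == 1) ds <- matrix(ds, nrow = 1, dimnames = list(NULL, domains))
  out <- data.frame(respondent = m$respondent_ids[!incomplete],
                    ds, total = rowSums(r),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("shs_scores", "data.frame")
  out
}

#' Median-split stratification into optimal and suboptimal status
#'
#' Respondents are labelled by comparing their total score with the sample
#' median: totals strictly above the median are `suboptimal`, totals strictly
#' below are `optimal`. Scores tied with the median go to the group named by
#' `ties` (default `"optimal"`, i.e. only a total strictly greater than the
#' cutoff marks suboptimal status).
#'
#' @param scores An `shs_scores` table from [shs_scores()].
#' @param ties Which group receives totals equal to the cutoff:
#'   `"optimal"` (default) or `"suboptimal"`.
#' @return The table with a `status` factor column added and attributes
#'   `median_cutoff` and `ties`.
#' @export
median_split <- function(scores, ties = c("optimal", "suboptimal")) {
  stopifnot(inherits(scores, "shs_scores"))
  ties <- match.arg(ties)
  if (nrow(scores) < 2)
    stop("median split needs at least 2 respondents", call. = FALSE)
  cutoff <- stats::median(scores$total)
  if (all(scores$total == scores$total[1])) {
    warning("degenerate split: all total scores identical; ",
            "labelling every respondent optimal", call. = FALSE)
    status <- rep("optimal", nrow(scores))
  } else if (ties == "optimal") {
    status <- ifelse(scores$total > cutoff, "suboptimal", "optimal")
  } else {
    status <- ifelse(scores$total >= cutoff, "suboptimal", "optimal")
  }
  scores$status <- factor(status, levels = c("optimal", "suboptimal"))
  attr(scores, "median_cutoff") <- cutoff
  attr(scores, "ties") <- ties
  scores
}

#' Cohen's d from group summary statistics
#'
#' Pooled-standard-deviation standardised mean difference,
#' \deqn{d = |m_2 - m_1| / s_p,\quad
#'   s_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)},}
#' computable directly from printed summary tables. Symmetric in the two
#' groups and invariant to rescaling both groups by a common factor.
#'
#' @param m1,s1,n1 Mean, SD and size of the first group.
#' @param m2,s2,n2 Mean, SD and size of the second group.
#' @return The effect size (full precision) with attribute `label`, the
#'   conventional magnitude band from [effect_label()].
#' @export
#' @examples
#' round(cohens_d(53.09, 7.57, 106, 57.02, 10.43, 111), 2)  # 0.43
cohens_d <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) {
    if (m1 == m2) return(structure(0, label = "negligible"))
    stop("zero pooled SD with unequal means: effect size undefined",
         call. = FALSE)
  }
  d <- abs(m2 - m1) / sp
  structure(d, label = effect_label(d))
}

#' Conventional effect-size magnitude bands
#'
#' `|d| < 0.2` negligible, `[0.2, 0.5)` small, `[0.5, 0.8)` medium,
#' `>= 0.8` large.
#'
#' @param d Effect size(s).
#' @return Character vector of labels.
#' @export
effect_label <- function(d) {
  d <- abs(d)
  cut(d, breaks = c(-Inf, 0.2, 0.5, 0.8, Inf),
      labels = c("negligible", "small", "medium", "large"),
      right = FALSE)
}

#' Compare a covariate between the optimal and suboptimal groups
#'
#' Numeric covariates get a pooled-variance two-sample t-test plus Cohen's d
#' (the same pooled SD underlies both, so d and t are mutually consistent);
#' categorical covariates get a Pearson chi-square test on the contingency
#' table (no continuity correction).
#'
#' @param m A [likert_matrix()] carrying the covariate.
#' @param variable Covariate column name.
#' @param status Optional status factor aligned with respondents; computed
#'   via [shs_scores()] + [median_split()] when omitted.
#' @return A list of class `group_comparison`.
#' @export
compare_groups <- function(m, variable, status = NULL) {
  stopifnot(inherits(m, "likert_matrix"))
  if (is.null(m$covariates) || !variable %in% names(m$covariates))
    stop("covariate not found: ", variable, call. = FALSE)
  if (is.null(status)) {
    sc <- median_split(shs_scores(m))
    status <- sc$status[match(m$respondent_ids, sc$respondent)]
  }
  status <- factor(status, levels = c("optimal", "suboptimal"))
  x <- m$covariates[[variable]]
  keep <- !is.na(x) & !is.na(status)
  x <- x[keep]; status <- droplevels(status[keep])
  if (nlevels(status) < 2 || any(table(status) < 2))
    stop("insufficient data: each status group needs n >= 2", call. = FALSE)

  if (is.numeric(x)) {
    g1 <- x[status == "optimal"]; g2 <- x[status == "suboptimal"]
    tt <- stats::t.test(g2, g1, var.equal = TRUE)
    d <- cohens_d(mean(g1), stats::sd(g1), length(g1),
                  mean(g2), stats::sd(g2), length(g2))
    out <- list(variable = variable, type = "numeric",
                group_means = c(optimal = mean(g1), suboptimal = mean(g2)),
                group_sds = c(optimal = stats::sd(g1),
                              suboptimal = stats::sd(g2)),
                group_ns = c(optimal = length(g1), suboptimal = length(g2)),
                statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, cohens_d = as.numeric(d),
                effect_label = as.character(attr(d, "label")))
  } else {
    tab <- table(status, x)
    ct <- stats::chisq.test(tab, correct = FALSE)
    out <- list(variable = variable, type = "categorical", table = tab,
                statistic = unname(ct$statistic), df = unname(ct$parameter),
                p_value = ct$p.value, cohens_d = NA_real_,
                effect_label = NA_character_)
  }
  class(out) <- "group_comparison"
  out
}

#' Compare groups from printed summary statistics
#'
#' Recomputes the pooled two-sample t-test and Cohen's d from group means,
#' SDs and sizes alone, as needed when only a summary table is available.
#'
#' @inheritParams cohens_d
#' @return A `group_comparison` list.
#' @export
compare_groups_from_summaries <- function(m1, s1, n1, m2, s2, n2) {
  d <- cohens_d(m1, s1, n1, m2, s2, n2)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  tstat <- (m2 - m1) / (sp * sqrt(1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(variable = NA_character_, type = "numeric",
                 group_means = c(optimal = m1, suboptimal = m2),
                 group_sds = c(optimal = s1, suboptimal = s2),
                 group_ns = c(optimal = n1, suboptimal = n2),
                 statistic = tstat, df = df, p_value = p,
                 cohens_d = as.numeric(d),
                 effect_label = as.character(attr(d, "label"))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$type == "numeric") {
    cat(sprintf("%s: optimal %.2f +/- %.2f (n=%d) vs suboptimal %.2f +/- %.2f (n=%d)\n",
                x$variable, x$group_means[1], x$group_sds[1], x$group_ns[1],
                x$group_means[2], x$group_sds[2], x$group_ns[2]))
    cat(sprintf("  t = %.2f on df = %d, p = %.3g; d = %.2f (%s)\n",
                x$statistic, x$df, x$p_value, x$cohens_d, x$effect_label))
  } else {
    cat(sprintf("%s: chi-square = %.2f on df = %d, p = %.3g\n",
                x$variable, x$statistic, x$df, x$p_value))
  }
  invisible(x)
}

#' Published cohort summary table
#'
#' The packaged group-level summary statistics (means, SDs, group sizes and
#' printed effect sizes) of the questionnaire's validation cohort, for
#' recomputing effect sizes and tests from summaries.
#'
#' @return A list with elements `groups`, `numeric` (data frame) and
#'   `categorical`.
#' @export
shsq25_cohort_summaries <- function() {
  path <- system.file("extdata", "shsq25_cohort_summaries.json",
                      package = "shsnet")
  jsonlite::read_json(path, simplifyVector = TRUE)
}
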