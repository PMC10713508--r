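#' Random sparse ground-truth partial-correlation network
#'
#' Draws a symmetric sparsity pattern of the requested density, assigns edge
#' weights (partial correlations) from `weight_range` with a configurable
#' fraction of negative signs, and repairs the implied precision matrix to
#' positive definiteness by a uniform eigenvalue shift followed by
#' re-standardisation to unit diagonal. The repair shrinks weights slightly;
#' the realised weights and density are recorded.
#'
#' @param p Number of nodes (items), at least 2.
#' @param density Target fraction of nonzero off-diagonal pairs in `[0, 1]`.
#' @param weight_range Interval for edge-weight magnitudes.
#' @param prob_negative Probability an edge weight is negative (default
#'   0.15: questionnaire networks are predominantly positive).
#' @param seed Integer seed; generation is reproducible from `(seed, args)`.
#' @param min_eigen Smallest eigenvalue enforced on the precision matrix.
#' @return An object of class `shs_truth` with elements `pcor` (partial
#'   correlations, zero diagonal), `sigma` (implied correlation matrix,
#'   positive definite, unit diagonal), `density` (realised), `p`, `seed`.
#' @export
#' @examples
#' tr <- shs_truth(p = 10, density = 0.2, seed = 1)
#' tr$density
shs_truth <- function(p = 25, density = 0.19, weight_range = c(0.15, 0.4),
                      prob_negative = 0.15, seed = NULL, min_eigen = 0.05) {
  stopifnot(p >= 2, density >= 0, density <= 1,
            length(weight_range) == 2, all(weight_range >= 0))
  if (!is.null(seed)) set.seed(seed)
  npairs <- p * (p - 1) / 2
  nedges <- round(density * npairs)
  K <- diag(p)
  if (nedges > 0) {
    sel <- sample.int(npairs, nedges)
    w <- stats::runif(nedges, weight_range[1], weight_range[2]) *
      ifelse(stats::runif(nedges) < prob_negative, -1, 1)
    P <- matrix(0, p, p)
    P[upper.tri(P)][sel] <- w
    P <- P + t(P)
    K <- diag(p) - P
  }
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < min_eigen) {
    K <- K + (min_eigen - min(ev)) * diag(p)
    K <- stats::cov2cor(K)
  }
  if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("cannot reach a positive definite precision matrix; ",
         "use smaller weights or lower density", call. = FALSE)
  pcor <- -K
  diag(pcor) <- 0
  sigma <- stats::cov2cor(solve(K))
  labels <- if (p == 25) shsq25_items()$item else sprintf("V%02d", seq_len(p))
  dimnames(pcor) <- dimnames(sigma) <- list(labels, labels)
  structure(list(pcor = pcor, sigma = sigma, p = p,
                 density = sum(pcor[upper.tri(pcor)] != 0) / npairs,
                 seed = seed),
            class = "shs_truth")
}

#' @export
print.shs_truth <- function(x, ...) {
  cat(sprintf("Ground-truth network: p = %d, density = %.3f (%d edges)\n",
              x$p, x$density, sum(x$pcor[upper.tri(x$pcor)] != 0)))
  invisible(x)
}

#' Cohort preset: target item marginals
#'
#' Per-item target means and SDs on the 0--4 scale. The packaged presets
#' `"optimal_like"` and `"suboptimal_like"` carry the published per-item
#' response means/SDs of the two study populations; `"custom"` takes
#' user-supplied targets.
#'
#' @param name `"optimal_like"`, `"suboptimal_like"` or `"custom"`.
#' @param n Number of respondents to generate (defaults to the published
#'   group size for the packaged presets).
#' @param mean,sd Per-item targets, required for `"custom"`.
#' @return A list of class `cohort_preset`.
#' @export
cohort_preset <- function(name = c("optimal_like", "suboptimal_like", "custom"),
                          n = NULL, mean = NULL, sd = NULL) {
  name <- match.arg(name)
  if (name == "custom") {
    stopifnot(!is.null(mean), !is.null(sd), length(mean) == length(sd),
              !is.null(n))
    items <- names(mean) %||% sprintf("V%02d", seq_along(mean))
  } else {
    pre <- .load_presets()[[name]]
    mean <- pre$mean; sd <- pre$sd
    items <- .load_presets()$items
    if (is.null(n)) n <- pre$n
  }
  stopifnot(all(mean >= 0), all(mean <= 4), all(sd > 0), n >= 1)
  structure(list(name = name, n = as.integer(n),
                 mean = stats::setNames(mean, items),
                 sd = stats::setNames(sd, items)),
            class = "cohort_preset")
}

# Discretisation thresholds for one item: a latent N(0,1) cut at qnorm of the
# cumulative category probabilities of a N(mu, sd) binned at half-integers,
# with mu tuned by 1-D root finding so the binned mean hits the target.
.fit_thresholds <- function(target_mean, target_sd) {
  if (target_mean <= 0 || target_mean >= 4)
    stop("target mean ", target_mean,
         " is not reachable by a 0..4 item with finite thresholds",
         call. = FALSE)
  binned_mean <- function(mu) {
    cuts <- pnorm(c(0.5, 1.5, 2.5, 3.5), mu, target_sd)
    pr <- diff(c(0, cuts, 1))
    sum(0:4 * pr)
  }
  mu <- stats::uniroot(function(m) binned_mean(m) - target_mean,
                       lower = -15, upper = 19, tol = 1e-10)$root
  cum <- pnorm(c(0.5, 1.5, 2.5, 3.5), mu, target_sd)
  cum <- pmin(pmax(cum, 1e-12), 1 - 1e-12)
  stats::qnorm(cum)
}

#' Generate an ordinal cohort from a ground-truth network
#'
#' Gaussian-copula generator: a latent multivariate normal sample with the
#' truth's correlation matrix is discretised column by column through
#' thresholds fitted so each item's expected mean matches the preset target.
#' Target SDs are not matched exactly (they are emergent from the mean, the
#' latent scale and the thresholding).
#'
#' @param truth An [shs_truth()] whose dimension equals the preset's item
#'   count.
#' @param preset A [cohort_preset()].
#' @param seed Integer seed.
#' @return A [likert_matrix()] with a `population` covariate naming the
#'   preset.
#' @export
generate_cohort <- function(truth, preset, seed = NULL) {
  stopifnot(inherits(truth, "shs_truth"), inherits(preset, "cohort_preset"))
  if (truth$p != length(preset$mean))
    stop("truth dimension (", truth$p, ") != preset item count (",
         length(preset$mean), ")", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Z <- MASS::mvrnorm(preset$n, mu = rep(0, truth$p), Sigma = truth$sigma)
  if (preset$n == 1) Z <- matrix(Z, nrow = 1)
  R <- matrix(0L, preset$n, truth$p,
              dimnames = list(NULL, names(preset$mean)))
  for (j in seq_len(truth$p)) {
    tau <- .fit_thresholds(preset$mean[j], preset$sd[j])
    R[, j] <- findInterval(Z[, j], tau)
  }
  likert_matrix(R, covariates = data.frame(
    population = rep(preset$name, preset$n), stringsAsFactors = FALSE))
}

#' @rdname generate_cohort
#' @param object An `shs_truth` object.
#' @param nsim Number of cohorts.
#' @param ... Unused.
#' @export
simulate.shs_truth <- function(object, nsim = 1, seed = NULL,
                               preset = cohort_preset("suboptimal_like"),
                               ...) {
  out <- lapply(seq_len(nsim), function(i)
    generate_cohort(object, preset,
                    seed = if (is.null(seed)) NULL else seed + i - 1L))
  if (nsim == 1) out[[1]] else out
}

#' Structure-recovery metrics of an estimated network against the truth
#'
#' Sensitivity is the fraction of true edges recovered, specificity the
#' fraction of true non-edges kept at zero, and `weight_correlation` the
#' Pearson correlation between estimated and true weights over the true-edge
#' pairs.
#'
#' @param estimate An [shs_network()] (or partial-correlation matrix).
#' @param truth An [shs_truth()].
#' @return A list with `sensitivity`, `specificity`, `weight_correlation`
#'   (each `NA` when undefined, e.g. a truth with no edges).
#' @export
recovery_metrics <- function(estimate, truth) {
  W <- if (inherits(estimate, "shs_network")) estimate$weights else estimate
  stopifnot(inherits(truth, "shs_truth"), all(dim(W) == dim(truth$pcor)))
  lt <- lower.tri(W)
  est <- W[lt]; tru <- truth$pcor[lt]
  true_edge <- tru != 0
  sens <- if (any(true_edge)) mean(est[true_edge] != 0) else NA_real_
  spec <- if (any(!true_edge)) mean(est[!true_edge] == 0) else NA_real_
  wcor <- if (sum(true_edge) >= 2 && stats::sd(est[true_edge]) > 0)
    stats::cor(est[true_edge], tru[true_edge]) else NA_real_
  list(sensitivity = sens, specificity = spec, weight_correlation = wcor)
}
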