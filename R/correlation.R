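#' Two-step polychoric correlation of an ordinal pair
#'
#' Estimates the latent bivariate-normal correlation behind two ordinal
#' variables: thresholds come first from the marginal cumulative proportions
#' via the inverse normal CDF, then rho maximises the bivariate-normal
#' cell-probability likelihood of the observed contingency table with the
#' thresholds held fixed. Categories with an entirely empty row/column of
#' the table are collapsed (with a message). rho is constrained to
#' `(-0.999, 0.999)`.
#'
#' @param x,y Integer/ordinal vectors of equal length with at least two
#'   observed categories each.
#' @return A list with `rho`, `thresholds_x`, `thresholds_y`.
#' @export
#' @examples
#' set.seed(1)
#' z <- MASS::mvrnorm(500, c(0, 0), matrix(c(1, .6, .6, 1), 2))
#' polychoric_pair(findInterval(z[, 1], c(-1, 0, 1)),
#'                 findInterval(z[, 2], c(-1, 0, 1)))$rho
polychoric_pair <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) ||
      any(x[!is.na(x)] != round(x[!is.na(x)])) ||
      any(y[!is.na(y)] != round(y[!is.na(y)])))
    stop("polychoric correlation needs integer-coded ordinal input",
         call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  tab <- table(x, y)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("each variable needs at least 2 observed categories", call. = FALSE)
  # empty margins cannot occur from table() on observed values, but guard
  # against caller-supplied tables routed through .polychoric_from_table
  .polychoric_from_table(tab)
}

.polychoric_from_table <- function(tab, cap = 0.999) {
  tab <- as.matrix(tab)
  drop_r <- rowSums(tab) == 0
  drop_c <- colSums(tab) == 0
  if (any(drop_r) || any(drop_c)) {
    message("collapsing ", sum(drop_r) + sum(drop_c),
            " empty categor(ies) in the contingency table")
    tab <- tab[!drop_r, !drop_c, drop = FALSE]
  }
  n <- sum(tab)
  tx <- stats::qnorm(cumsum(rowSums(tab) / n))[-nrow(tab)]
  ty <- stats::qnorm(cumsum(colSums(tab) / n))[-ncol(tab)]
  opt <- stats::optimize(function(r) .polychoric_negll_cpp(tab, tx, ty, r),
                         interval = c(-cap, cap), tol = 1e-8)
  list(rho = opt$minimum, thresholds_x = unname(tx),
       thresholds_y = unname(ty), negll = opt$objective)
}

#' Zero-order correlation matrix for ordinal items
#'
#' Pairwise association matrix by the chosen method, with pairwise-complete
#' handling of missing entries, perfect-association clipping at 0.999, and
#' positive-definite repair via [nearest_pd()] when required (flagged).
#' Items on an ordinal 0--4 scale default to the polychoric estimator;
#' Pearson and Spearman are available for sensitivity analysis.
#'
#' @param m A [likert_matrix()] or numeric matrix (columns = items).
#' @param method `"polychoric"` (default), `"spearman"` or `"pearson"`.
#' @param pd_tolerance Smallest eigenvalue accepted before repair (default
#'   1e-4, keeping repaired matrices well conditioned for the estimator).
#' @return An object of class `shs_cor`: `values` (symmetric, unit
#'   diagonal), `labels`, `method`, `n_effective` (minimum pairwise n),
#'   `pd_repaired`.
#' @export
correlation_matrix <- function(m, method = c("polychoric", "spearman",
                                             "pearson"),
                               pd_tolerance = 1e-4) {
  method <- match.arg(method)
  X <- if (inherits(m, "likert_matrix")) m$ratings else as.matrix(m)
  p <- ncol(X)
  if (sum(stats::complete.cases(X)) < 3)
    stop("insufficient data: need at least 3 complete respondents",
         call. = FALSE)
  n_levels <- apply(X, 2, function(v) length(unique(v[!is.na(v)])))
  if (any(n_levels < 2))
    stop("constant item(s): ",
         paste(colnames(X)[n_levels < 2], collapse = ", "), call. = FALSE)

  cap <- 0.999
  if (method == "polychoric") {
    R <- diag(p)
    for (j in seq_len(p - 1)) for (k in (j + 1):p) {
      R[j, k] <- R[k, j] <- polychoric_pair(X[, j], X[, k])$rho
    }
  } else {
    R <- stats::cor(X, method = method, use = "pairwise.complete.obs")
  }
  degenerate <- abs(R[upper.tri(R)]) > cap
  if (any(degenerate)) {
    warning(sum(degenerate), " item pair(s) with near-perfect association ",
            "clipped at ", cap, call. = FALSE)
    R[abs(R) > cap & row(R) != col(R)] <-
      cap * sign(R[abs(R) > cap & row(R) != col(R)])
  }
  diag(R) <- 1
  dimnames(R) <- list(colnames(X), colnames(X))
  pairwise_n <- crossprod(!is.na(X))
  repaired <- FALSE
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <
      pd_tolerance) {
    R <- nearest_pd(R, tol = pd_tolerance)
    repaired <- TRUE
  }
  structure(list(values = R, labels = colnames(X), method = method,
                 n_effective = min(pairwise_n), pd_repaired = repaired),
            class = "shs_cor")
}

#' @export
print.shs_cor <- function(x, ...) {
  cat(sprintf("%s correlation matrix: %d items, n_effective = %d%s\n",
              x$method, length(x$labels), x$n_effective,
              if (x$pd_repaired) " (PD-repaired)" else ""))
  invisible(x)
}

#' Nearest positive-definite correlation matrix by eigenvalue clipping
#'
#' Clips eigenvalues below `tol`, reconstructs, rescales to unit diagonal,
#' and repeats until the smallest eigenvalue clears `tol` (the rescaling can
#' push it back slightly). Already-PD input is returned unchanged, so the
#' operation is idempotent. The Frobenius distance to the input is attached
#' as attribute `frobenius_distance`.
#'
#' @param values Symmetric matrix.
#' @param tol Eigenvalue floor.
#' @return Symmetric positive definite matrix with unit diagonal.
#' @export
nearest_pd <- function(values, tol = 1e-8) {
  if (!isSymmetric(unname(values), tol = 1e-8))
    stop("input must be symmetric", call. = FALSE)
  orig <- values
  values <- (values + t(values)) / 2
  for (i in 1:100) {
    e <- eigen(values, symmetric = TRUE)
    if (min(e$values) >= tol) break
    values <- e$vectors %*% diag(pmax(e$values, tol)) %*% t(e$vectors)
    values <- stats::cov2cor(values)
  }
  diag(values) <- 1
  dimnames(values) <- dimnames(orig)
  attr(values, "frobenius_distance") <- sqrt(sum((values - orig)^2))
  values
}
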