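#' Nonparametric bootstrap of edge weights
#'
#' Resamples respondents with replacement `B` times and re-runs the entire
#' estimation pipeline (correlation matrix, penalty path, EBIC selection)
#' per resample, yielding per-edge 95% quantile confidence intervals and
#' replicate strength centralities. Replicates whose resample leaves an
#' item constant (estimation impossible) are dropped and counted; more than
#' 10% dropped aborts.
#'
#' @param m A [likert_matrix()] or numeric data matrix.
#' @param B Number of bootstrap samples (default 500; below 100 a warning
#'   is issued).
#' @param seed Integer seed; the ensemble is reproducible from
#'   `(data, config, seed)`.
#' @param conf_level Confidence level of the quantile intervals.
#' @param ... Estimation settings passed to [shs_network()] (identical for
#'   every replicate).
#' @return An object of class `shs_boot`: `edge_weights` (B x pairs matrix
#'   of replicate weights), `strengths` (B x p), `cis` (edge, estimate,
#'   lower, upper), `original` (the point-estimate network), `B`,
#'   `n_dropped`, `seed`.
#' @export
bootstrap_edges <- function(m, B = 500, seed = NULL, conf_level = 0.95, ...) {
  X <- if (inherits(m, "likert_matrix")) m$ratings else as.matrix(m)
  if (B < 100) warning("B < 100 gives unreliable quantile intervals",
                       call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  original <- shs_network(X, ...)
  p <- ncol(X); n <- nrow(X)
  lt <- lower.tri(original$weights)
  pair_names <- outer(original$labels, original$labels,
                      function(a, b) paste(b, a, sep = "--"))[lt]
  ew <- matrix(NA_real_, B, sum(lt), dimnames = list(NULL, pair_names))
  st <- matrix(NA_real_, B, p, dimnames = list(NULL, original$labels))
  dropped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    net_b <- tryCatch(shs_network(X[idx, , drop = FALSE], ...),
                      error = function(e) NULL)
    if (is.null(net_b)) { dropped <- dropped + 1L; next }
    ew[b, ] <- net_b$weights[lt]
    st[b, ] <- rowSums(abs(net_b$weights))
  }
  if (dropped > 0.10 * B)
    stop("estimation failed in ", dropped, " of ", B,
         " bootstrap replicates", call. = FALSE)
  ok <- !is.na(ew[, 1])
  a <- (1 - conf_level) / 2
  qs <- apply(ew[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(a, 1 - a))
  cis <- data.frame(edge = pair_names, estimate = original$weights[lt],
                    lower = qs[1, ], upper = qs[2, ], row.names = NULL)
  structure(list(edge_weights = ew[ok, , drop = FALSE],
                 strengths = st[ok, , drop = FALSE],
                 cis = cis, original = original, B = B,
                 n_dropped = dropped, conf_level = conf_level, seed = seed),
            class = "shs_boot")
}

#' @export
print.shs_boot <- function(x, ...) {
  cat(sprintf("Bootstrap ensemble: B = %d (%d dropped), %d edges, %d%% CIs\n",
              x$B, x$n_dropped, ncol(x$edge_weights),
              round(100 * x$conf_level)))
  invisible(x)
}

#' Bootstrapped difference tests between edges or centralities
#'
#' For every pair of edges (or node strengths) the bootstrap distribution
#' of their difference is formed across replicates; a pair is flagged as
#' significantly different when the `1 - alpha` quantile interval of the
#' difference excludes zero.
#'
#' @param ens An [bootstrap_edges()] ensemble.
#' @param alpha Significance level (default 0.05).
#' @param target `"edges"` or `"centrality"` (node strength).
#' @return A logical symmetric matrix of class `difference_matrix`; `TRUE`
#'   means the pair differs significantly.
#' @export
difference_tests <- function(ens, alpha = 0.05,
                             target = c("edges", "centrality")) {
  stopifnot(inherits(ens, "shs_boot"))
  target <- match.arg(target)
  M <- if (target == "edges") ens$edge_weights else ens$strengths
  k <- ncol(M)
  out <- matrix(FALSE, k, k, dimnames = list(colnames(M), colnames(M)))
  pr <- c(alpha / 2, 1 - alpha / 2)
  for (i in seq_len(k - 1)) {
    d <- M[, (i + 1):k, drop = FALSE] - M[, i]
    qs <- apply(d, 2, stats::quantile, probs = pr)
    sig <- qs[1, ] > 0 | qs[2, ] < 0
    out[i, (i + 1):k] <- sig
    out[(i + 1):k, i] <- sig
  }
  class(out) <- c("difference_matrix", class(out))
  out
}

#' Case-dropping (subsetting) bootstrap for centrality stability
#'
#' For each drop proportion q, draws `B_per_level` subsamples without
#' replacement of size floor((1-q) n), re-estimates the network end to end,
#' and records the Pearson correlation between each centrality index of the
#' subset network and the same index in the full-sample network. The grid
#' is truncated (with a warning) where the retained sample would fall below
#' `min_n`.
#'
#' @param m A [likert_matrix()] or data matrix.
#' @param proportions Drop-proportion grid (default 0.05 to 0.75 by 0.05).
#' @param B_per_level Subsamples per proportion (default 50).
#' @param seed Integer seed.
#' @param indices Centrality indices to track.
#' @param min_n Smallest admissible retained sample (default 20).
#' @param ... Estimation settings passed to [shs_network()].
#' @return An object of class `shs_stability`: `curves` (tidy data frame:
#'   proportion, replicate, index, correlation), `original` centralities,
#'   `proportions`, `B_per_level`, `seed`.
#' @export
case_drop_stability <- function(m, proportions = seq(0.05, 0.75, by = 0.05),
                                B_per_level = 50, seed = NULL,
                                indices = c("strength", "closeness",
                                            "betweenness"),
                                min_n = 20, ...) {
  X <- if (inherits(m, "likert_matrix")) m$ratings else as.matrix(m)
  n <- nrow(X)
  keep <- floor((1 - proportions) * n) >= min_n
  if (!all(keep)) {
    warning("truncating drop grid: retained n would fall below ", min_n,
            call. = FALSE)
    proportions <- proportions[keep]
  }
  if (length(proportions) == 0)
    stop("drop grid empty after truncation", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  original <- shs_network(X, ...)
  cent0 <- centrality_indices(original)
  rows <- vector("list", length(proportions) * B_per_level)
  r <- 0L
  for (q in proportions) {
    size <- floor((1 - q) * n)
    for (b in seq_len(B_per_level)) {
      r <- r + 1L
      idx <- sample.int(n, size)
      net_b <- tryCatch(shs_network(X[idx, , drop = FALSE], ...),
                        error = function(e) NULL)
      if (is.null(net_b)) next
      cent_b <- centrality_indices(net_b)
      cors <- vapply(indices, function(ix) {
        a <- cent0[[ix]]; v <- cent_b[[ix]]
        if (stats::sd(a) == 0 || stats::sd(v) == 0) return(NA_real_)
        stats::cor(a, v)
      }, numeric(1))
      rows[[r]] <- data.frame(proportion = q, replicate = b,
                              index = indices, correlation = unname(cors))
    }
  }
  curves <- do.call(rbind, rows)
  structure(list(curves = curves, original = cent0,
                 proportions = proportions, B_per_level = B_per_level,
                 seed = seed),
            class = "shs_stability")
}

#' @export
print.shs_stability <- function(x, ...) {
  cs <- cs_coefficient(x)
  cat("Case-dropping stability over q in [",
      min(x$proportions), ",", max(x$proportions), "]\n")
  cat("  CS(0.7):",
      paste(sprintf("%s = %.2f", names(cs), cs), collapse = ", "), "\n")
  invisible(x)
}

#' Correlation-stability (CS) coefficient
#'
#' The largest drop proportion q in the grid at which the empirical
#' `1 - certainty` quantile of the subset-vs-original centrality
#' correlations still reaches `corr_threshold`; 0 when no grid point
#' qualifies. The conventional reading: CS(0.7) should exceed 0.25, and
#' preferably 0.5, for a centrality order to be called stable.
#'
#' @param res An [case_drop_stability()] result.
#' @param corr_threshold Correlation to retain (default 0.7).
#' @param certainty Certainty level (default 0.95).
#' @return Named numeric vector, one CS value per centrality index.
#' @export
cs_coefficient <- function(res, corr_threshold = 0.7, certainty = 0.95) {
  stopifnot(inherits(res, "shs_stability"))
  curves <- res$curves[!is.na(res$curves$correlation), ]
  indices <- unique(res$curves$index)
  if (nrow(curves) == 0) {
    warning("no usable drop-curves (degenerate centralities in every ",
            "replicate); CS undefined", call. = FALSE)
    return(stats::setNames(rep(NA_real_, length(indices)), indices))
  }
  vapply(indices, function(ix) {
    sub <- curves[curves$index == ix, ]
    if (nrow(sub) == 0) return(NA_real_)
    qs <- sort(unique(sub$proportion))
    lowq <- vapply(qs, function(q)
      stats::quantile(sub$correlation[sub$proportion == q],
                      probs = 1 - certainty, names = FALSE), numeric(1))
    ok <- qs[lowq >= corr_threshold]
    if (length(ok) == 0) 0 else max(ok)
  }, numeric(1))
}
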