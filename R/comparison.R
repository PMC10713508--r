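#' Permutation-based two-group network comparison
#'
#' Estimates a network per group, then builds the permutation null by
#' pooling the respondents, reshuffling the group labels with the group
#' sizes preserved exactly, and re-estimating both networks for each
#' permutation. Two connectivity statistics are available: the absolute
#' difference in global strength (overall connectivity) and the maximum
#' absolute edge-weight difference. P-values use the add-one estimator
#' \eqn{p = (1 + \#\{stat_{perm} \ge stat_{obs}\}) / (1 + n_{perm})}, so
#' they are never zero and the test is valid (conservative) under the
#' null. The weighted-adjacency correlation between the two observed
#' networks is reported alongside.
#'
#' @param mA,mB [likert_matrix()] objects (or data matrices) with the same
#'   items.
#' @param n_perm Number of label permutations (default 1000).
#' @param statistics Subset of `c("global_strength_diff", "max_edge_diff")`.
#' @param seed Integer seed.
#' @param ... Estimation settings passed to [shs_network()] (shared by both
#'   groups and all permutations).
#' @return An object of class `shs_nct`: observed global strengths,
#'   observed statistics, p-values, `adjacency_correlation`, `n_perm`,
#'   `seed`, and the permutation null distributions.
#' @export
network_comparison_test <- function(mA, mB, n_perm = 1000,
                                    statistics = c("global_strength_diff",
                                                   "max_edge_diff"),
                                    seed = NULL, ...) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  XA <- if (inherits(mA, "likert_matrix")) mA$ratings else as.matrix(mA)
  XB <- if (inherits(mB, "likert_matrix")) mB$ratings else as.matrix(mB)
  if (!identical(colnames(XA), colnames(XB)))
    stop("the two groups must share the same items", call. = FALSE)
  if (min(nrow(XA), nrow(XB)) < 20)
    warning("a group has n < 20; the comparison will be unstable",
            call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  stat_fun <- function(netA, netB) {
    out <- c()
    if ("global_strength_diff" %in% statistics)
      out["global_strength_diff"] <-
        abs(global_strength(netA) - global_strength(netB))
    if ("max_edge_diff" %in% statistics)
      out["max_edge_diff"] <- max(abs(netA$weights - netB$weights))
    out
  }
  netA <- shs_network(XA, ...)
  netB <- shs_network(XB, ...)
  observed <- stat_fun(netA, netB)
  adj_cor <- tryCatch(adjacency_correlation(netA, netB),
                      error = function(e) {
                        warning(conditionMessage(e), call. = FALSE)
                        NA_real_
                      })

  pool <- rbind(XA, XB)
  nA <- nrow(XA); nTot <- nrow(pool)
  null_mat <- matrix(NA_real_, n_perm, length(observed),
                     dimnames = list(NULL, names(observed)))
  failed <- 0L
  for (k in seq_len(n_perm)) {
    ord <- sample.int(nTot)
    idx <- ord[seq_len(nA)]
    res <- tryCatch({
      nA_k <- shs_network(pool[idx, , drop = FALSE], ...)
      nB_k <- shs_network(pool[ord[-seq_len(nA)], , drop = FALSE], ...)
      stat_fun(nA_k, nB_k)
    }, error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    null_mat[k, ] <- res
  }
  if (failed > 0.10 * n_perm)
    stop("estimation failed in ", failed, " of ", n_perm, " permutations",
         call. = FALSE)
  ok <- !is.na(null_mat[, 1])
  pvals <- vapply(names(observed), function(s)
    (1 + sum(null_mat[ok, s] >= observed[s])) / (1 + sum(ok)), numeric(1))
  structure(list(global_strength = c(A = global_strength(netA),
                                     B = global_strength(netB)),
                 observed = observed, p_values = pvals,
                 adjacency_correlation = adj_cor,
                 n_perm = sum(ok), n_failed = failed,
                 null_distributions = null_mat[ok, , drop = FALSE],
                 networks = list(A = netA, B = netB), seed = seed),
            class = "shs_nct")
}

#' @export
print.shs_nct <- function(x, ...) {
  cat(sprintf("Network comparison test (%d permutations)\n", x$n_perm))
  cat(sprintf("  global strength: A = %.3f, B = %.3f\n",
              x$global_strength[1], x$global_strength[2]))
  for (s in names(x$observed))
    cat(sprintf("  %s = %.3f, p = %.4f\n", s, x$observed[s],
                x$p_values[s]))
  cat(sprintf("  adjacency correlation r = %.3f\n",
              x$adjacency_correlation))
  invisible(x)
}

#' Correlation of two weighted adjacency matrices
#'
#' Pearson correlation between the vectorised lower triangles of the two
#' networks' weight matrices, zeros included — a global similarity measure
#' of network structure.
#'
#' @param netA,netB [shs_network()] objects (or weight matrices) on the
#'   same labels.
#' @return A single correlation.
#' @export
adjacency_correlation <- function(netA, netB) {
  WA <- if (inherits(netA, "shs_network")) netA$weights else as.matrix(netA)
  WB <- if (inherits(netB, "shs_network")) netB$weights else as.matrix(netB)
  if (!all(dim(WA) == dim(WB)))
    stop("networks have different dimensions", call. = FALSE)
  a <- WA[lower.tri(WA)]; b <- WB[lower.tri(WB)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("adjacency correlation undefined: zero variance in a weight vector",
         call. = FALSE)
  stats::cor(a, b)
}
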