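#' Fit a regularised partial-correlation network
#'
#' The package's core model fit. From ordinal item responses (or a
#' ready-made correlation matrix) it estimates a sparse Gaussian graphical
#' model: graphical lasso along a log-spaced penalty path, penalty selected
#' by minimising the extended BIC with hyperparameter `gamma` (default 0.5,
#' the conventional EBICglasso setting), and the selected precision matrix
#' \eqn{\Theta} converted to partial correlations
#' \eqn{\rho_{ij} = -\theta_{ij}/\sqrt{\theta_{ii}\theta_{jj}}} — the edge
#' weights of the network. EBIC ties are broken toward the larger penalty
#' (the sparser model). The fit is deterministic: identical inputs give a
#' bit-identical network.
#'
#' @param x A [likert_matrix()], a numeric respondent-by-item matrix, or an
#'   `shs_cor` correlation matrix (then `n` is required).
#' @param n Sample size; only needed when `x` is a correlation matrix.
#' @param method Correlation method when `x` is raw data; see
#'   [correlation_matrix()].
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambdas,lambda_min_ratio Penalty path; see [lambda_path()].
#' @param penalize_diagonal,tol,maxit Passed to the graphical lasso.
#' @return An object of class `shs_network`: `weights` (symmetric partial
#'   correlations, zero diagonal), `theta` (selected precision matrix),
#'   `labels`, `lambda`, `ebic`, `path` (per-lambda criterion and edge
#'   counts), `n`, `gamma`, and provenance (`method`, `config`).
#' @seealso [network_summary()], [centrality_indices()],
#'   [node_predictability()], [bootstrap_edges()]
#' @export
#' @examples
#' truth <- shs_truth(p = 8, density = 0.25, seed = 42)
#' pre <- cohort_preset("custom", n = 300, mean = rep(1.5, 8), sd = rep(1, 8))
#' cohort <- generate_cohort(truth, pre, seed = 1)
#' net <- shs_network(cohort, method = "spearman", n_lambdas = 40)
#' net
shs_network <- function(x, n = NULL,
                        method = c("polychoric", "spearman", "pearson"),
                        gamma = 0.5, n_lambdas = 100, lambda_min_ratio = 0.01,
                        penalize_diagonal = FALSE, tol = 1e-6, maxit = 10000) {
  method <- match.arg(method)
  stopifnot(gamma >= 0, n_lambdas >= 2,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  if (inherits(x, "shs_cor")) {
    S <- x
    if (is.null(n)) stop("supply the sample size n with a correlation matrix",
                         call. = FALSE)
  } else {
    nr <- if (inherits(x, "likert_matrix")) nrow(x$ratings) else nrow(x)
    S <- correlation_matrix(x, method = method)
    n <- nr
  }
  p <- length(S$labels)
  if (n < p)
    warning("n (", n, ") < number of items (", p,
            "): estimates may be unstable", call. = FALSE)

  lambdas <- lambda_path(S, n_lambdas = n_lambdas,
                         lambda_min_ratio = lambda_min_ratio)
  path <- .glasso_path_cpp(S$values, lambdas, penalize_diagonal, tol, maxit)
  if (!all(path$converged))
    stop("graphical lasso failed to converge at ",
         sum(!path$converged), " penalty value(s)", call. = FALSE)
  ebic <- -n * path$loglik_term + path$nedges * log(n) +
    4 * gamma * path$nedges * log(p)
  sel <- which.min(ebic)  # path is descending, so the first minimum is the
                          # sparsest among tied models
  theta <- path$theta[[sel]]
  dimnames(theta) <- list(S$labels, S$labels)
  w <- -stats::cov2cor(theta)
  w <- (w + t(w)) / 2  # cov2cor can leave last-ulp asymmetry
  diag(w) <- 0
  dimnames(w) <- list(S$labels, S$labels)
  structure(list(weights = w, theta = theta, labels = S$labels,
                 lambda = lambdas[sel], lambda_index = sel,
                 ebic = ebic[sel],
                 path = data.frame(lambda = lambdas, ebic = ebic,
                                   edges = as.integer(path$nedges)),
                 n = n, gamma = gamma, method = S$method,
                 pd_repaired = isTRUE(S$pd_repaired),
                 config = list(n_lambdas = n_lambdas,
                               lambda_min_ratio = lambda_min_ratio,
                               penalize_diagonal = penalize_diagonal,
                               tol = tol, maxit = maxit)),
            class = "shs_network")
}

#' @rdname shs_network
#' @param S An `shs_cor` object (alias interface mirroring the estimator
#'   stage of the pipeline).
#' @param ... Passed on to [shs_network()].
#' @export
estimate_network <- function(S, n, ...) shs_network(S, n = n, ...)

#' @export
print.shs_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("Regularised partial-correlation network (%s, EBIC gamma = %g)\n",
              x$method, x$gamma))
  cat(sprintf("  %d nodes, %d/%d edges (density %.3f), lambda = %.4f, n = %d\n",
              length(x$labels), s$edge_count, s$possible_edges, s$density,
              x$lambda, x$n))
  invisible(x)
}

#' @export
summary.shs_network <- function(object, ...) {
  s <- network_summary(object)
  s$global_strength <- global_strength(object)
  s$lambda <- object$lambda
  s$ebic <- object$ebic
  s$n <- object$n
  class(s) <- "summary.shs_network"
  s
}

#' @export
print.summary.shs_network <- function(x, ...) {
  cat(sprintf(paste0("edges: %d / %d  density: %.3f\n",
                     "mean |weight| over edges: %.3f  global strength: %.3f\n",
                     "lambda: %.4f  EBIC: %.2f  n: %d\n"),
              x$edge_count, x$possible_edges, x$density,
              x$mean_abs_nonzero_weight, x$global_strength,
              x$lambda, x$ebic, x$n))
  invisible(x)
}

#' @export
coef.shs_network <- function(object, ...) object$weights

#' Edge counts, density and mean edge weight of a network
#'
#' Density is the number of nonzero (lower-triangle) edges over the
#' \eqn{p(p-1)/2} possible pairs. "Mean edge weight" averages, by default,
#' absolute values over the nonzero edges; signed-over-nonzero and
#' absolute-over-all-pairs variants are selectable since the convention
#' differs between reports.
#'
#' @param net An [shs_network()] (or weight matrix).
#' @param weight_mean One of `"abs_nonzero"` (default), `"signed_nonzero"`,
#'   `"abs_all"`.
#' @return A list of class `network_summary`: `edge_count`,
#'   `possible_edges`, `density`, `mean_abs_nonzero_weight` (0 with an
#'   `empty` flag for an edgeless network).
#' @export
#' @examples
#' w <- matrix(0, 25, 25)
#' w[upper.tri(w)][1:58] <- 0.05
#' network_summary(w + t(w))$density  # 58/300
network_summary <- function(net, weight_mean = c("abs_nonzero",
                                                 "signed_nonzero",
                                                 "abs_all")) {
  weight_mean <- match.arg(weight_mean)
  W <- if (inherits(net, "shs_network")) net$weights else as.matrix(net)
  p <- ncol(W)
  wl <- W[lower.tri(W)]
  edge_count <- sum(wl != 0)
  possible <- p * (p - 1) / 2
  mw <- if (edge_count == 0) 0 else switch(weight_mean,
    abs_nonzero = mean(abs(wl[wl != 0])),
    signed_nonzero = mean(wl[wl != 0]),
    abs_all = mean(abs(wl)))
  structure(list(edge_count = edge_count, possible_edges = possible,
                 density = edge_count / possible,
                 mean_abs_nonzero_weight = mw,
                 empty = edge_count == 0),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("%d / %d edges, density %.3f, mean edge weight %.3f\n",
              x$edge_count, x$possible_edges, x$density,
              x$mean_abs_nonzero_weight))
  invisible(x)
}

#' Global strength of a network
#'
#' Overall connectivity: the sum of absolute edge weights over unordered
#' node pairs.
#'
#' @param net An [shs_network()] or weight matrix.
#' @return A single number.
#' @export
global_strength <- function(net) {
  W <- if (inherits(net, "shs_network")) net$weights else as.matrix(net)
  sum(abs(W[lower.tri(W)]))
}

#' Plot a fitted network
#'
#' Draws the weighted graph with either the seeded Fruchterman-Reingold
#' layout or the ordinal MDS configuration of the zero-order correlations.
#' Edge width scales with |weight|; solid edges are positive, dashed
#' negative.
#'
#' @param x An [shs_network()].
#' @param layout `"fr"` (default) or a 2-column coordinate matrix (e.g.
#'   from [ordinal_mds()]).
#' @param seed Layout seed.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.shs_network <- function(x, layout = "fr", seed = 1, ...) {
  coords <- if (is.matrix(layout)) layout else fr_layout(x, seed = seed)
  W <- x$weights
  p <- ncol(W)
  graphics::plot(coords, type = "n", xlab = "", ylab = "", axes = FALSE,
                 asp = 1, ...)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (W[i, j] != 0)
      graphics::segments(coords[i, 1], coords[i, 2], coords[j, 1],
                         coords[j, 2],
                         lwd = 0.5 + 6 * abs(W[i, j]),
                         lty = if (W[i, j] > 0) 1 else 2,
                         col = if (W[i, j] > 0) "forestgreen" else "firebrick")
  }
  graphics::points(coords, pch = 21, bg = "grey90", cex = 2.4)
  graphics::text(coords, labels = x$labels, cex = 0.55)
  invisible(coords)
}

#' Export a network to standard formats
#'
#' @param net An [shs_network()].
#' @param path Output file.
#' @param format `"tsv"` (edge list: node_a, node_b, weight), `"csv"`
#'   (labelled weight matrix), `"json"` (nodes, edges, lambda, EBIC,
#'   provenance) or `"graphml"`.
#' @export
write_network <- function(net, path, format = c("tsv", "csv", "json",
                                                "graphml")) {
  stopifnot(inherits(net, "shs_network"))
  format <- match.arg(format)
  W <- net$weights
  idx <- which(lower.tri(W) & W != 0, arr.ind = TRUE)
  edges <- data.frame(node_a = net$labels[idx[, 2]],
                      node_b = net$labels[idx[, 1]],
                      weight = W[idx])
  switch(format,
    tsv = utils::write.table(edges, path, sep = "\t", quote = FALSE,
                             row.names = FALSE),
    csv = utils::write.csv(as.data.frame(W), path),
    json = jsonlite::write_json(
      list(nodes = net$labels, edges = edges, lambda = net$lambda,
           ebic = net$ebic, n = net$n, gamma = net$gamma,
           method = net$method, config = net$config),
      path, auto_unbox = TRUE, digits = NA),
    graphml = {
      g <- .as_igraph(net)
      igraph::write_graph(g, path, format = "graphml")
    })
  invisible(path)
}

.as_igraph <- function(net, abs_weights = FALSE) {
  W <- abs(net$weights)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!abs_weights) {
    # restore signs as an edge attribute
    el <- igraph::as_edgelist(g, names = FALSE)
    igraph::E(g)$sign <- sign(net$weights[el])
  }
  g
}
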