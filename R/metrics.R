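#' Node centrality indices of a weighted network
#'
#' Strength is the sum of absolute edge weights at a node. Path-based
#' indices use the standard psychometric-network distance transform
#' \eqn{d_{ij} = 1/|w_{ij}|} on present edges: closeness is the reciprocal
#' of the total shortest-path distance from a node to the other nodes of
#' its connected component (cross-component distances are excluded, not set
#' to infinity; component sizes are reported), and betweenness counts the
#' shortest paths passing through a node. Each index is also returned
#' z-standardised across nodes, and the pairwise correlations among the
#' three raw indices are attached.
#'
#' @param net An [shs_network()] or symmetric weight matrix.
#' @return A data frame of class `centrality_table` (node, component,
#'   component_size, strength, closeness, betweenness and their `_z`
#'   versions) with attribute `index_correlations`.
#' @export
centrality_indices <- function(net) {
  W <- if (inherits(net, "shs_network")) net$weights else as.matrix(net)
  p <- ncol(W)
  stopifnot(p >= 2)
  labels <- colnames(W) %||% sprintf("V%02d", seq_len(p))
  strength <- rowSums(abs(W))
  if (all(W == 0)) {
    warning("empty network: all centralities are zero", call. = FALSE)
    out <- data.frame(node = labels, component = seq_len(p),
                      component_size = 1L,
                      strength = 0, closeness = 0, betweenness = 0,
                      strength_z = 0, closeness_z = 0, betweenness_z = 0)
    class(out) <- c("centrality_table", "data.frame")
    attr(out, "index_correlations") <- matrix(NA_real_, 3, 3,
      dimnames = rep(list(c("strength", "closeness", "betweenness")), 2))
    return(out)
  }
  A <- abs(W)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  dmat <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  comp <- igraph::components(g)
  closeness <- vapply(seq_len(p), function(i) {
    same <- which(comp$membership == comp$membership[i])
    same <- setdiff(same, i)
    if (length(same) == 0) return(0)
    1 / sum(dmat[i, same])
  }, numeric(1))
  betweenness <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                                     directed = FALSE)
  zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else
    rep(0, length(v))
  out <- data.frame(node = labels,
                    component = comp$membership,
                    component_size = comp$csize[comp$membership],
                    strength = strength, closeness = closeness,
                    betweenness = unname(betweenness),
                    strength_z = zs(strength), closeness_z = zs(closeness),
                    betweenness_z = zs(unname(betweenness)))
  rownames(out) <- NULL
  class(out) <- c("centrality_table", "data.frame")
  attr(out, "index_correlations") <- suppressWarnings(
    stats::cor(out[, c("strength", "closeness", "betweenness")]))
  out
}

#' Node predictability from the fitted precision matrix
#'
#' The proportion of a node's variance explained by its neighbours. On the
#' correlation scale the residual variance of node j given all others is
#' \eqn{1/\theta_{jj}}, so predictability is \eqn{1 - 1/\theta_{jj}},
#' clipped to `[0, 1]`; an isolated node gets 0. This analytic definition
#' equals the \eqn{R^2} of regressing each standardised variable on all
#' others when no penalty is applied. An empirical nodewise-regression
#' refit (`method = "refit"`, regressing each item on its selected
#' neighbours in the raw data) is provided as a cross-check.
#'
#' @param net An [shs_network()].
#' @param method `"analytic"` (default) or `"refit"`.
#' @param data Raw data ([likert_matrix()] or matrix), required for
#'   `"refit"`.
#' @return A data frame of class `predictability_table` (node,
#'   predictability) with attribute `mean`.
#' @export
node_predictability <- function(net, method = c("analytic", "refit"),
                                data = NULL) {
  stopifnot(inherits(net, "shs_network"))
  method <- match.arg(method)
  if (method == "analytic") {
    pred <- 1 - 1 / diag(net$theta)
  } else {
    if (is.null(data)) stop("refit predictability needs the raw data",
                            call. = FALSE)
    X <- if (inherits(data, "likert_matrix")) data$ratings else
      as.matrix(data)
    X <- scale(X)
    pred <- vapply(seq_along(net$labels), function(j) {
      nb <- which(net$weights[, j] != 0)
      if (length(nb) == 0) return(0)
      fit <- stats::lm.fit(cbind(1, X[, nb, drop = FALSE]), X[, j])
      1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    }, numeric(1))
  }
  pred <- pmin(pmax(unname(pred), 0), 1)
  out <- data.frame(node = net$labels, predictability = pred)
  class(out) <- c("predictability_table", "data.frame")
  attr(out, "mean") <- mean(pred)
  out
}

#' Network-level mean predictability
#'
#' Arithmetic mean of per-node predictability, rounded to two decimals for
#' reporting (the full-precision value is kept as an attribute).
#'
#' @param table A `predictability_table` from [node_predictability()], or a
#'   numeric vector of per-node values.
#' @return Rounded mean with attribute `full_precision`.
#' @export
#' @examples
#' predictability_summary(c(0.61, 0.78, 0.67, 0.56, 0.48))  # 0.62
predictability_summary <- function(table) {
  v <- if (is.data.frame(table)) table$predictability else as.numeric(table)
  if (length(v) == 0) stop("empty predictability table", call. = FALSE)
  m <- mean(v)
  structure(round(m, 2), full_precision = m)
}
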