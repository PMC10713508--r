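#' Correlations to dissimilarities for scaling
#'
#' \eqn{d_{ij} = \sqrt{1 - |r_{ij}|}} by default, so strongly associated
#' items (of either sign) are placed close together, matching connectivity
#' semantics; `signed = TRUE` uses \eqn{\sqrt{1 - r_{ij}}} instead.
#'
#' @param R An `shs_cor` object or correlation matrix.
#' @param signed Use the signed transform.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
corr_to_dissimilarity <- function(R, signed = FALSE) {
  Rm <- if (inherits(R, "shs_cor")) R$values else as.matrix(R)
  D <- if (signed) sqrt(pmax(1 - Rm, 0)) else sqrt(pmax(1 - abs(Rm), 0))
  diag(D) <- 0
  D
}

#' Ordinal (non-metric) multidimensional scaling
#'
#' Stress-majorisation (SMACOF) with monotone regression: each cycle fits
#' disparities to the configuration distances by isotonic regression on the
#' rank order of the input dissimilarities (ties pooled), rescales them to
#' the distance norm, and applies the Guttman transform. Only the rank
#' order of the dissimilarities matters, so any strictly increasing
#' transform of an exactly representable input leaves the solution (and the
#' near-zero stress) unchanged. The initial configuration is the classical
#' (metric) scaling solution, making the result deterministic; `seed` only
#' perturbs degenerate starts.
#'
#' @param D Symmetric non-negative dissimilarity matrix, zero diagonal.
#' @param dim Embedding dimension (default 2).
#' @param seed Seed for degenerate-start perturbation.
#' @param max_iter,tol Iteration cap and relative stress-decrease
#'   tolerance.
#' @return An object of class `shs_mds`: `points` (node coordinates),
#'   `stress` (Kruskal stress-1), `shepard` (dissimilarity, distance,
#'   disparity triples), `stress_trajectory`, `iterations`, `converged`.
#' @export
ordinal_mds <- function(D, dim = 2, seed = NULL, max_iter = 500,
                        tol = 1e-10) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  if (any(D < 0) || any(diag(D) != 0))
    stop("dissimilarities must be non-negative with zero diagonal",
         call. = FALSE)
  p <- nrow(D)
  lt <- lower.tri(D)
  delta <- D[lt]
  X <- tryCatch(stats::cmdscale(D, k = dim), error = function(e) NULL)
  if (is.null(X) || !is.matrix(X) || ncol(X) < dim ||
      any(apply(X, 2, stats::sd) < 1e-12)) {
    if (!is.null(seed)) set.seed(seed)
    X <- matrix(stats::rnorm(p * dim, sd = 0.1), p, dim)
  }
  ord <- order(delta)
  dist_lt <- function(X) {
    dm <- as.matrix(stats::dist(X))
    dm[lt]
  }
  stress1 <- function(d, dhat) sqrt(sum((d - dhat)^2) / sum(d^2))

  d <- dist_lt(X)
  traj <- numeric(0)
  converged <- FALSE
  iter <- 0
  stress_old <- Inf
  dhat <- d
  repeat {
    iter <- iter + 1
    # optimal monotone disparities given the configuration
    iso <- stats::isoreg(d[ord])
    dhat[ord] <- iso$yf
    dhat <- dhat * sqrt(sum(d^2) / sum(dhat^2))
    s <- stress1(d, dhat)
    traj <- c(traj, s)
    if (is.finite(stress_old) &&
        (stress_old - s) < tol * max(stress_old, 1e-12)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    stress_old <- s
    # Guttman transform
    Dhat <- matrix(0, p, p); Dhat[lt] <- dhat
    Dhat <- Dhat + t(Dhat)
    Dm <- matrix(0, p, p); Dm[lt] <- d
    Dm <- Dm + t(Dm)
    ratio <- ifelse(Dm > 0, Dhat / Dm, 0)
    B <- -ratio
    diag(B) <- rowSums(ratio)
    X <- (B %*% X) / p
    d <- dist_lt(X)
  }
  rownames(X) <- rownames(D) %||% sprintf("V%02d", seq_len(p))
  shepard <- data.frame(dissimilarity = delta[ord], distance = d[ord],
                        disparity = dhat[ord])
  structure(list(points = X, stress = traj[length(traj)],
                 shepard = shepard, stress_trajectory = traj,
                 iterations = iter, converged = converged, dim = dim),
            class = "shs_mds")
}

#' @export
print.shs_mds <- function(x, ...) {
  cat(sprintf("Ordinal MDS (%d-D): stress-1 = %.4g after %d iterations%s\n",
              x$dim, x$stress, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
plot.shs_mds <- function(x, shepard = FALSE, ...) {
  if (shepard) {
    graphics::plot(x$shepard$dissimilarity, x$shepard$distance,
                   xlab = "dissimilarity", ylab = "configuration distance",
                   pch = 16, col = "grey50", ...)
    graphics::lines(x$shepard$dissimilarity, x$shepard$disparity,
                    col = "firebrick", lwd = 2, type = "s")
  } else {
    graphics::plot(x$points, pch = 21, bg = "grey90", cex = 2.2,
                   xlab = "", ylab = "", asp = 1, ...)
    graphics::text(x$points, labels = rownames(x$points), cex = 0.55)
  }
  invisible(x)
}

#' Seeded Fruchterman-Reingold layout
#'
#' Force-directed node placement with absolute edge weights as attraction
#' strengths; deterministic for a fixed seed.
#'
#' @param net An [shs_network()] or weight matrix.
#' @param seed Integer seed (default 1).
#' @param iterations Iterations of the force simulation.
#' @return A p x 2 coordinate matrix with node labels as row names.
#' @export
fr_layout <- function(net, seed = 1, iterations = 500) {
  W <- if (inherits(net, "shs_network")) net$weights else as.matrix(net)
  g <- igraph::graph_from_adjacency_matrix(abs(W), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  coords <- igraph::layout_with_fr(g, niter = iterations,
                                   weights = if (igraph::ecount(g) > 0)
                                     igraph::E(g)$weight else NULL)
  rownames(coords) <- colnames(W) %||% sprintf("V%02d", seq_len(ncol(W)))
  coords
}
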