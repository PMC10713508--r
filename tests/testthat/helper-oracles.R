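# Independent oracles and small fixture builders used across the suite.

# penalised negative log-likelihood the graphical lasso minimises
penalised_objective <- function(theta, S, lambda) {
  ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) return(1e10)
  off <- theta; diag(off) <- 0
  -determinant(theta)$modulus[1] + sum(S * theta) + lambda * sum(abs(off))
}

# brute-force numeric minimiser of the penalised objective over symmetric
# matrices (Nelder-Mead, two restarts), independent of the solver under test
glasso_numeric_oracle <- function(S, lambda, start) {
  p <- ncol(S)
  ltri <- lower.tri(start, diag = TRUE)
  obj <- function(v) {
    th <- matrix(0, p, p)
    th[ltri] <- v
    th <- th + t(th) - diag(diag(th))
    penalised_objective(th, S, lambda)
  }
  set.seed(99)
  starts <- list(solve(S)[ltri], diag(p)[ltri],
                 start[ltri] + stats::rnorm(sum(ltri), 0, 0.01))
  best <- NULL
  for (v in starts) {
    cand <- stats::optim(v, obj, method = "Nelder-Mead",
                         control = list(maxit = 50000, reltol = 1e-15))
    for (k in 1:3)
      cand <- stats::optim(cand$par, obj, method = "Nelder-Mead",
                           control = list(maxit = 50000, reltol = 1e-15))
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  # polish on the smooth manifold: freeze the zero pattern the search found,
  # then quasi-Newton on the remaining coordinates (objective is smooth there)
  par <- best$par
  free <- abs(par) > 1e-5
  obj_sub <- function(v) {
    w <- par
    w[free] <- v
    w[!free] <- 0
    obj(w)
  }
  pol <- stats::optim(par[free], obj_sub, method = "BFGS",
                      control = list(maxit = 10000, reltol = 1e-15))
  if (pol$value <= best$value + 1e-12) {
    par[free] <- pol$par
    par[!free] <- 0
  }
  th <- matrix(0, p, p)
  th[ltri] <- par
  th + t(th) - diag(diag(th))
}

# all shortest paths between two nodes of a small weighted graph by
# exhaustive simple-path enumeration (p <= 7)
.all_paths <- function(adj, from, to, visited = from) {
  if (from == to) return(list(visited))
  out <- list()
  for (nxt in which(adj[from, ] > 0)) {
    if (nxt %in% visited) next
    out <- c(out, .all_paths(adj, nxt, to, c(visited, nxt)))
  }
  out
}

brute_betweenness <- function(W) {
  p <- ncol(W)
  dmat <- 1 / abs(W)
  dmat[W == 0] <- 0
  btw <- numeric(p)
  for (s in 1:(p - 1)) for (t in (s + 1):p) {
    paths <- .all_paths(abs(W), s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, function(pp)
      sum(dmat[cbind(pp[-length(pp)], pp[-1])]), numeric(1))
    shortest <- paths[abs(lens - min(lens)) < 1e-12]
    for (v in setdiff(1:p, c(s, t))) {
      thru <- mean(vapply(shortest, function(pp) v %in% pp, logical(1)))
      btw[v] <- btw[v] + thru
    }
  }
  btw
}

# Procrustes distance up to translation, rotation/reflection and scaling,
# relative to the norm of the centred target
procrustes_distance <- function(X, target) {
  Xc <- scale(X, scale = FALSE)
  Tc <- scale(target, scale = FALSE)
  sv <- svd(t(Tc) %*% Xc)
  R <- sv$v %*% t(sv$u)
  s <- sum(sv$d) / sum(Xc^2)
  sqrt(sum((s * Xc %*% R - Tc)^2) / sum(Tc^2))
}

# deterministic 25-item ratings block with every item showing spread
make_ratings25 <- function(n = 8, seed = 1) {
  set.seed(seed)
  items <- shsq25_items()$item
  m <- matrix(sample(0:4, n * 25, replace = TRUE), n, 25,
              dimnames = list(NULL, items))
  m
}

# independent ordinal items (no latent structure)
rlikert_independent <- function(n, p, seed,
                                probs = c(0.35, 0.3, 0.2, 0.1, 0.05)) {
  set.seed(seed)
  matrix(sample(0:4, n * p, replace = TRUE, prob = probs), n, p,
         dimnames = list(NULL, sprintf("V%02d", 1:p)))
}

# small synthetic cohort for resampling/comparison tests
make_cohort <- function(p = 6, n = 150, seed = 71, density = 0.3) {
  tr <- shs_truth(p = p, density = density, seed = seed)
  pre <- cohort_preset("custom", n = n, mean = rep(1.5, p), sd = rep(1, p))
  generate_cohort(tr, pre, seed = seed + 1)
}

# stability object with hand-chosen correlation curves
fake_stability <- function(curve, B = 40) {
  rows <- do.call(rbind, lapply(names(curve), function(q) {
    data.frame(proportion = as.numeric(q), replicate = seq_len(B),
               index = "strength", correlation = curve[[q]])
  }))
  structure(list(curves = rows, original = NULL,
                 proportions = as.numeric(names(curve)),
                 B_per_level = B, seed = NULL),
            class = "shs_stability")
}

# minimal fitted-network object from a known precision matrix
net_from_theta <- function(theta, n = 100) {
  w <- -stats::cov2cor(theta)
  diag(w) <- 0
  labels <- colnames(theta)
  if (is.null(labels)) {
    labels <- sprintf("V%02d", seq_len(ncol(theta)))
    dimnames(theta) <- dimnames(w) <- list(labels, labels)
  }
  structure(list(weights = w, theta = theta, labels = labels,
                 lambda = 0, ebic = NA_real_, n = n, gamma = 0.5,
                 method = "pearson", config = list()),
            class = "shs_network")
}
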