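# Independent oracles used across the suite. These deliberately use different
# algorithms from the package: proximal gradient instead of block coordinate
# descent for the penalized likelihood, and exhaustive simple-path enumeration
# instead of Dijkstra/Brandes for the distance-based centralities.

# Proximal-gradient (ISTA) maximizer of
#   log det Theta - tr(S Theta) - lam * sum_{i != j} |theta_ij|
# with backtracking line search; converges to the unique optimum of this
# concave problem.
ista_glasso <- function(S, lam, max_iter = 50000, tol = 1e-9) {
  p <- nrow(S)
  theta <- diag(1 / diag(S))
  obj <- function(Th) {
    ch <- tryCatch(chol(Th), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    2 * sum(log(diag(ch))) - sum(S * Th) - lam * sum(abs(Th - diag(diag(Th))))
  }
  soft <- function(Th, t) {
    out <- sign(Th) * pmax(abs(Th) - t, 0)
    diag(out) <- diag(Th)
    out
  }
  t_step <- 1
  f_old <- obj(theta)
  for (it in seq_len(max_iter)) {
    grad <- solve(theta) - S            # gradient of the smooth part
    repeat {
      cand <- soft(theta + t_step * grad, t_step * lam)
      f_new <- obj(cand)
      if (is.finite(f_new) && f_new >= f_old - 1e-14) break
      t_step <- t_step / 2
      if (t_step < 1e-12) break
    }
    if (max(abs(cand - theta)) < tol) { theta <- cand; break }
    theta <- cand
    f_old <- f_new
  }
  (theta + t(theta)) / 2
}

# Random correlation matrix from n_gen latent normal rows.
random_corr <- function(p, seed, n_gen = 30) {
  set.seed(seed)
  cor(matrix(rnorm(n_gen * p), n_gen, p))
}

# Random sparse symmetric weight matrix in (-1, 1), zero diagonal.
random_weights <- function(p, seed, density = 0.6) {
  set.seed(seed)
  w <- matrix(0, p, p)
  up <- which(upper.tri(w))
  on <- runif(length(up)) < density
  w[up] <- on * runif(length(up), 0.1, 0.9) * sample(c(-1, 1), length(up), TRUE)
  w <- w + t(w)
  dimnames(w) <- list(paste0("V", 1:p), paste0("V", 1:p))
  w
}

# All simple paths between two vertices of a small graph, as vertex index
# vectors (including endpoints).
all_simple_paths <- function(adj, from, to) {
  p <- nrow(adj)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == to) { paths[[length(paths) + 1]] <<- path; return() }
    for (u in seq_len(p))
      if (adj[v, u] && !(u %in% path)) walk(c(path, u))
  }
  walk(from)
  paths
}

path_cost <- function(path, cost) {
  sum(cost[cbind(path[-length(path)], path[-1])])
}

# Exhaustive shortest-distance matrix by path enumeration.
oracle_distances <- function(w, alpha) {
  p <- nrow(w)
  cost <- ifelse(abs(w) > 0, (1 / abs(w))^alpha, Inf)
  adj <- abs(w) > 0
  d <- matrix(Inf, p, p); diag(d) <- 0
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    paths <- all_simple_paths(adj, i, j)
    if (length(paths) > 0)
      d[i, j] <- d[j, i] <- min(vapply(paths, path_cost, numeric(1), cost = cost))
  }
  d
}

oracle_closeness <- function(w, alpha) {
  d <- oracle_distances(w, alpha)
  tot <- rowSums(d)
  ifelse(is.finite(tot) & tot > 0, 1 / tot, 0)
}

# Betweenness by enumeration: for each pair (j, k), all co-minimal simple
# paths (within tie_tol of the minimum) are counted; vertex i scores the
# fraction passing through it as an intermediate.
oracle_betweenness <- function(w, alpha, tie_tol = 1e-10) {
  p <- nrow(w)
  cost <- ifelse(abs(w) > 0, (1 / abs(w))^alpha, Inf)
  adj <- abs(w) > 0
  bc <- rep(0, p)
  for (j in seq_len(p - 1)) for (k in (j + 1):p) {
    paths <- all_simple_paths(adj, j, k)
    if (length(paths) == 0) next
    costs <- vapply(paths, path_cost, numeric(1), cost = cost)
    minimal <- paths[costs <= min(costs) + tie_tol]
    g <- length(minimal)
    for (i in seq_len(p)) {
      if (i == j || i == k) next
      g_i <- sum(vapply(minimal, function(pp) i %in% pp[-c(1, length(pp))],
                        logical(1)))
      bc[i] <- bc[i] + g_i / g
    }
  }
  bc
}

# Direct double-loop evaluation of the Zhang-Horvath formula.
oracle_clustering <- function(w) {
  p <- nrow(w)
  a <- abs(w)
  if (max(a) == 0) return(rep(0, p))
  wh <- a / max(a)
  out <- rep(0, p)
  for (i in seq_len(p)) {
    num <- 0
    for (j in seq_len(p)) for (k in seq_len(p))
      if (j != k) num <- num + wh[i, j] * wh[j, k] * wh[i, k]
    den <- sum(wh[i, ])^2 - sum(wh[i, ]^2)
    out[i] <- if (den > 0) num / den else 0
  }
  out
}

# Latent Gaussian draws from a known ground truth, used by recovery checks.
latent_draws <- function(truth, n, seed) {
  set.seed(seed)
  z <- matrix(rnorm(n * nrow(truth$true_covariance)), n) %*%
    chol(truth$true_covariance)
  colnames(z) <- truth$topics
  z
}
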