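#' Weighted network from a partial-correlation matrix
#'
#' Wraps a symmetric signed weight matrix (zero = no edge) as a
#' `weighted_network`. Centrality and clustering computations use absolute
#' weights — shortest-path costs and triangle products are undefined for
#' negative weights — while the signed matrix is kept for reporting.
#'
#' @param weights p x p symmetric numeric matrix, zero diagonal, entries in
#'   (-1, 1); typically `net$partial` from [ebic_glasso_select()].
#' @param labels vertex labels; defaults to the matrix dimnames.
#' @return object of class `weighted_network` with components `labels`,
#'   `weights` (signed), `N`.
#' @export
weighted_network <- function(weights, labels = rownames(weights)) {
  weights <- unclass(weights)
  if (!is_square_symmetric(weights)) stopf("weights must be symmetric")
  if (any(diag(weights) != 0)) stopf("diagonal must be zero")
  if (any(abs(weights) >= 1)) stopf("edge weights must lie in (-1, 1)")
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(weights)))
  structure(list(labels = labels, weights = weights, N = nrow(weights)),
            class = "weighted_network")
}

as_weighted_network <- function(net) {
  if (inherits(net, "weighted_network")) return(net)
  if (inherits(net, "network_estimate"))
    return(weighted_network(net$partial, net$topics))
  if (is.matrix(net)) return(weighted_network(net))
  stopf("cannot interpret object of class %s as a network", class(net)[1])
}

#' Strength centrality
#'
#' Per-vertex sum of absolute edge weights, \eqn{s_i = \sum_j |w_{ij}|}: the
#' degree to which a vertex is directly connected to the rest of the network.
#'
#' @param net a `weighted_network`, `network_estimate`, or weight matrix.
#' @return named numeric vector of strengths.
#' @export
strength <- function(net) {
  net <- as_weighted_network(net)
  stats::setNames(rowSums(abs(net$weights)), net$labels)
}

edge_costs <- function(net, alpha) {
  a <- abs(net$weights)
  cost <- matrix(Inf, net$N, net$N)
  cost[a > 0] <- (1 / a[a > 0])^alpha
  diag(cost) <- 0
  cost
}

# Dijkstra from one source on a dense cost matrix; returns distances.
dijkstra_dist <- function(cost, src) {
  p <- nrow(cost)
  dist <- rep(Inf, p); dist[src] <- 0
  done <- rep(FALSE, p)
  for (step in seq_len(p)) {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    relax <- which(is.finite(cost[u, ]) & !done)
    nd <- dist[u] + cost[u, relax]
    upd <- nd < dist[relax]
    dist[relax[upd]] <- nd[upd]
  }
  dist
}

#' Weighted shortest-path distances
#'
#' Distance matrix under edge traversal cost \eqn{(1/|w_{ij}|)^\alpha},
#' computed by Dijkstra's algorithm. Stronger edges are shorter; the tuning
#' parameter `alpha` controls how strongly weight differences are felt.
#' Unreachable pairs get `Inf`.
#'
#' @param net a `weighted_network`, `network_estimate`, or weight matrix.
#' @param alpha positive tuning parameter (default 1).
#' @return p x p symmetric distance matrix, zero diagonal.
#' @export
weighted_distances <- function(net, alpha = 1) {
  net <- as_weighted_network(net)
  if (alpha <= 0) stopf("alpha must be positive")
  cost <- edge_costs(net, alpha)
  d <- t(vapply(seq_len(net$N), function(s) dijkstra_dist(cost, s),
                numeric(net$N)))
  d <- (d + t(d)) / 2
  dimnames(d) <- list(net$labels, net$labels)
  d
}

#' Closeness centrality
#'
#' \eqn{C_c(i) = [\sum_j d(i, j)]^{-1}} with weighted shortest-path distances
#' from [weighted_distances()]: the degree to which a vertex is indirectly
#' connected to all others. A vertex with any unreachable counterpart has an
#' infinite distance sum and closeness 0.
#'
#' @inheritParams weighted_distances
#' @return named numeric vector of closeness values.
#' @export
closeness <- function(net, alpha = 1) {
  net <- as_weighted_network(net)
  d <- weighted_distances(net, alpha)
  tot <- rowSums(d)
  out <- ifelse(is.finite(tot) & tot > 0, 1 / tot, 0)
  # single-vertex network: distance sum 0, define closeness 0
  stats::setNames(as.numeric(out), net$labels)
}

#' Betweenness centrality
#'
#' For each unordered pair (j, k) with \eqn{j \ne i \ne k}, the fraction of
#' weighted shortest j–k paths passing through vertex i, summed over pairs
#' (Brandes accumulation). Paths whose length is within `tie_tol` of the
#' minimum count as co-minimal.
#'
#' @inheritParams weighted_distances
#' @param tie_tol absolute tolerance for declaring two path lengths equal
#'   (default 1e-10).
#' @return named numeric vector of betweenness values.
#' @export
betweenness <- function(net, alpha = 1, tie_tol = 1e-10) {
  net <- as_weighted_network(net)
  if (alpha <= 0) stopf("alpha must be positive")
  p <- net$N
  cost <- edge_costs(net, alpha)
  bc <- rep(0, p)
  for (s in seq_len(p)) {
    dist <- dijkstra_dist(cost, s)
    ord <- order(dist)               # ascending; Inf last
    ord <- ord[is.finite(dist[ord])]
    sigma <- rep(0, p); sigma[s] <- 1
    preds <- vector("list", p)
    for (v in ord) {
      if (v == s) next
      pre <- which(is.finite(cost[, v]) & seq_len(p) != v &
                     abs(dist + cost[, v] - dist[v]) <= tie_tol)
      preds[[v]] <- pre
      sigma[v] <- sum(sigma[pre])
    }
    delta <- rep(0, p)
    for (v in rev(ord)) {
      if (v == s) next
      for (u in preds[[v]])
        delta[u] <- delta[u] + sigma[u] / sigma[v] * (1 + delta[v])
    }
    bc <- bc + ifelse(seq_len(p) == s, 0, delta)
  }
  stats::setNames(bc / 2, net$labels)   # each unordered pair counted twice
}

#' Zhang–Horvath weighted clustering coefficient
#'
#' With weights normalized to \eqn{\hat w = |w| / \max |w|}, the per-vertex
#' coefficient is
#' \deqn{C_i = \frac{\sum_{j \ne k} \hat w_{ij}\hat w_{jk}\hat w_{ik}}
#'                  {(\sum_j \hat w_{ij})^2 - \sum_j \hat w_{ij}^2},}
#' a weighted generalization of the local clustering coefficient lying in
#' [0, 1]. Vertices with fewer than two neighbors have a zero denominator and
#' are assigned 0.
#'
#' @param net a `weighted_network`, `network_estimate`, or weight matrix.
#' @return named numeric vector of clustering coefficients.
#' @export
clustering_zh <- function(net) {
  net <- as_weighted_network(net)
  a <- abs(net$weights)
  mx <- max(a)
  if (mx == 0) {
    warnf("network has no edges; clustering coefficients are all zero")
    return(stats::setNames(rep(0, net$N), net$labels))
  }
  w <- a / mx
  num <- diag(w %*% w %*% w)
  den <- rowSums(w)^2 - rowSums(w^2)
  out <- ifelse(den > 0, num / den, 0)
  stats::setNames(as.numeric(out), net$labels)
}

#' Centrality z-scores
#'
#' Standardizes each metric column across vertices: \eqn{(x - \bar x)/\sigma}
#' with the population (divide-by-N) standard deviation. Constant columns
#' yield all-zero z-scores with a warning.
#'
#' @param table data.frame with a `topic` column and numeric metric columns,
#'   as produced by [centrality_table()] with `zscores = FALSE`.
#' @param columns metric columns to standardize; default all numeric columns.
#' @return `table` with an appended `<metric>_z` column per metric.
#' @export
centrality_zscores <- function(table, columns = NULL) {
  if (nrow(table) < 2) stopf("need at least 2 vertices")
  if (is.null(columns))
    columns <- names(table)[vapply(table, is.numeric, logical(1))]
  for (cl in columns) {
    x <- table[[cl]]
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) {
      warnf("metric '%s' is constant across vertices; z-scores set to 0", cl)
      z <- rep(0, length(x))
    } else z <- (x - mean(x)) / s
    table[[paste0(cl, "_z")]] <- z
  }
  table
}

#' Centrality and clustering table for a network
#'
#' Computes strength, closeness, betweenness (all at the same `alpha`) and
#' the Zhang–Horvath clustering coefficient for every vertex, optionally with
#' per-metric z-scores.
#'
#' @param net a `weighted_network`, `network_estimate`, or weight matrix.
#' @param alpha tuning parameter for the distance-based indices (default 1).
#' @param zscores append z-score columns (default TRUE).
#' @return data.frame with columns `topic`, `strength`, `closeness`,
#'   `betweenness`, `clustering` (+ `_z` columns); attribute `alpha`.
#' @export
#' @examples
#' w <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
#' w["A", "B"] <- w["B", "A"] <- 0.5
#' w["B", "C"] <- w["C", "B"] <- 0.4
#' centrality_table(w)
centrality_table <- function(net, alpha = 1, zscores = TRUE) {
  net <- as_weighted_network(net)
  tab <- data.frame(
    topic = net$labels,
    strength = as.numeric(strength(net)),
    closeness = as.numeric(closeness(net, alpha)),
    betweenness = as.numeric(betweenness(net, alpha)),
    clustering = as.numeric(clustering_zh(net)),
    stringsAsFactors = FALSE
  )
  if (zscores)
    tab <- centrality_zscores(tab, c("strength", "closeness", "betweenness",
                                     "clustering"))
  attr(tab, "alpha") <- alpha
  tab
}

#' Write a centrality table as CSV
#'
#' @param table output of [centrality_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_centrality_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
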