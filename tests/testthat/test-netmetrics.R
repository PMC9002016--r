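two_node <- function(w12 = 0.5) {
  w <- matrix(c(0, w12, w12, 0), 2,
              dimnames = rep(list(c("A", "B")), 2))
  weighted_network(w)
}

test_that("strength sums absolute edge weights", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.2
  w[1, 3] <- w[3, 1] <- 0.3
  w[2, 3] <- w[3, 2] <- -0.4
  net <- weighted_network(w)
  expect_equal(unname(strength(net)), c(0.5, 0.6, 0.7, 0))
  # adding an edge never decreases strength
  w2 <- w; w2[1, 4] <- w2[4, 1] <- 0.1
  expect_true(all(strength(weighted_network(w2)) >= strength(net)))
})

test_that("distances use the inverse-weight cost with exponent alpha", {
  expect_equal(weighted_distances(two_node(0.5), alpha = 1)["A", "B"], 2)
  expect_equal(weighted_distances(two_node(0.5), alpha = 2)["A", "B"], 4)
  for (seed in 1:10) {
    w <- random_weights(5, seed)
    for (alpha in c(0.5, 1, 2))
      expect_equal(unname(weighted_distances(w, alpha)),
                   oracle_distances(w, alpha))
  }
})

test_that("distances agree with igraph on a random network", {
  skip_if_not_installed("igraph")
  w <- random_weights(7, seed = 42)
  cost <- ifelse(abs(w) > 0, 1 / abs(w), 0)
  g <- igraph::graph_from_adjacency_matrix(cost, mode = "undirected",
                                           weighted = TRUE)
  expect_equal(unname(weighted_distances(w, alpha = 1)),
               unname(igraph::distances(g, algorithm = "dijkstra")))
})

test_that("closeness inverts the distance sum and zeroes disconnected vertices", {
  expect_equal(unname(closeness(two_node(0.5), alpha = 1)), c(0.5, 0.5))
  # triangle with weights (0.5, 0.5, 0.25): hand-summed shortest distances
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.5
  w[1, 3] <- w[3, 1] <- 0.25
  # d(1,2) = 2, d(2,3) = 2, d(1,3) = min(4, 2+2) = 4
  expect_equal(unname(closeness(w, 1)), c(1 / 6, 1 / 4, 1 / 6))
  # isolated vertex makes every distance sum infinite
  w4 <- rbind(cbind(w, 0), 0)
  expect_equal(unname(closeness(w4, 1)), c(0, 0, 0, 0))
  for (seed in 1:5) {
    w <- random_weights(5, seed, density = 0.5)
    expect_equal(unname(closeness(w, 1)), oracle_closeness(w, 1))
  }
})

test_that("betweenness counts co-minimal path fractions", {
  # path graph A-B-C: B carries the single A-C path
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.5
  expect_equal(unname(betweenness(w, 1)), c(0, 1, 0))
  # complete triangle, equal weights: direct edges always win
  w[1, 3] <- w[3, 1] <- 0.5
  expect_equal(unname(betweenness(w, 1)), c(0, 0, 0))
  # exact ties split path counts: square with equal weights, two routes
  w <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
    w[e[1], e[2]] <- w[e[2], e[1]] <- 0.5
  expect_equal(unname(betweenness(w, 1)), rep(0.5, 4))
  for (seed in 1:10) {
    w <- random_weights(6, seed)
    expect_equal(unname(betweenness(w, 1)), oracle_betweenness(w, 1))
  }
})

test_that("Zhang-Horvath clustering matches its formula and conventions", {
  # equal-weight triangle: perfect transitivity
  w <- matrix(0.4, 3, 3); diag(w) <- 0
  expect_equal(unname(clustering_zh(w)), rep(1, 3))
  # star: center has no neighbor-neighbor edges
  w <- matrix(0, 4, 4)
  w[1, 2:4] <- w[2:4, 1] <- 0.5
  expect_equal(unname(clustering_zh(w)), rep(0, 4))
  # triangle with raw weights (0.6, 0.3, 0.3), hand evaluation
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.6
  w[1, 3] <- w[3, 1] <- 0.3
  w[2, 3] <- w[3, 2] <- 0.3
  expect_equal(unname(clustering_zh(w)), oracle_clustering(w))
  wh <- w / 0.6
  num1 <- 2 * wh[1, 2] * wh[2, 3] * wh[1, 3]
  den1 <- (wh[1, 2] + wh[1, 3])^2 - (wh[1, 2]^2 + wh[1, 3]^2)
  expect_equal(unname(clustering_zh(w))[1], num1 / den1)
  # empty network: all zero with a warning
  expect_warning(cz <- clustering_zh(matrix(0, 3, 3)), "no edges")
  expect_equal(unname(cz), rep(0, 3))
  # uniform weights reduce to the unweighted local clustering coefficient
  set.seed(77)
  adj <- matrix(0, 6, 6)
  up <- which(upper.tri(adj))
  adj[up] <- rbinom(length(up), 1, 0.6)
  adj <- adj + t(adj)
  w <- 0.3 * adj
  cz <- clustering_zh(w)
  for (i in 1:6) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) expect_equal(unname(cz[i]), 0)
    else {
      pairs <- combn(nb, 2)
      tri <- sum(adj[t(pairs)])
      expect_equal(unname(cz[i]), tri / ncol(pairs))
    }
  }
})

test_that("weight rescaling preserves distance-based structure", {
  w <- random_weights(6, seed = 3, density = 0.5)
  c_scale <- 0.6
  expect_equal(betweenness(w * c_scale, 1), betweenness(w, 1))
  expect_equal(order(closeness(w * c_scale, 1)), order(closeness(w, 1)))
  expect_equal(strength(w * c_scale), strength(w) * c_scale)
})

test_that("z-scores standardize with the population sd", {
  tab <- data.frame(topic = c("a", "b", "c"), m = c(1, 2, 3))
  z <- centrality_zscores(tab, "m")
  expect_equal(z$m_z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_warning(zc <- centrality_zscores(data.frame(topic = 1:3,
                                                     m = rep(2, 3)), "m"),
                 "constant")
  expect_equal(zc$m_z, rep(0, 3))
  set.seed(10)
  tab <- data.frame(topic = letters[1:8], m = rnorm(8))
  z <- centrality_zscores(tab, "m")$m_z
  expect_lt(abs(mean(z)), 1e-10)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-10)
})

test_that("centrality_table assembles all metrics for a network estimate", {
  truth <- make_partial_corr_model(generator_spec(p = 6, seed = 51))
  z <- latent_draws(truth, 500, seed = 52)
  net <- ebic_glasso_select(correlation_matrix(z))
  # this network is disconnected, so every closeness is 0 and its z-score
  # column warns about being constant
  tab <- suppressWarnings(centrality_table(net, alpha = 1))
  expect_equal(tab$topic, net$topics)
  expect_equal(tab$strength, unname(strength(net)))
  expect_equal(tab$betweenness, unname(betweenness(net, 1)))
  expect_true(all(c("strength_z", "closeness_z", "betweenness_z",
                    "clustering_z") %in% names(tab)))
  expect_true(all(tab$clustering >= 0 & tab$clustering <= 1))
  expect_true(all(tab$strength >= 0))
  N <- nrow(tab)
  expect_true(all(tab$betweenness >= 0 &
                    tab$betweenness <= (N - 1) * (N - 2) / 2))
})
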