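test_that("full shrinkage gives the empty network; p=2 at zero penalty is exact", {
  for (seed in 1:5) {
    S <- random_corr(4, seed)
    lam_max <- max(abs(S[upper.tri(S)]))
    fit <- glasso_fit(S, lam_max)
    expect_true(all(fit$precision[upper.tri(fit$precision)] == 0))
    # beyond lam_max too
    fit <- glasso_fit(S, lam_max * 1.5)
    expect_true(all(fit$precision[upper.tri(fit$precision)] == 0))
  }
  # two variables, no penalty: partial correlation equals the correlation
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  fit <- glasso_fit(S, 0, tol = 1e-12)
  expect_equal(precision_to_partial(fit$precision)[1, 2], 0.5,
               tolerance = 1e-10)
})

test_that("glasso solution matches the proximal-gradient oracle at p=3", {
  for (seed in 1:5) {
    S <- random_corr(3, seed)
    for (lam in c(0.02, 0.1)) {
      fit <- glasso_fit(S, lam, tol = 1e-10)
      oracle <- ista_glasso(S, lam)
      expect_lt(max(abs(fit$precision - oracle)), 1e-4)
    }
  }
})

test_that("converged fits invert their covariance", {
  S <- random_corr(6, seed = 12)
  fit <- glasso_fit(S, 0.05, tol = 1e-8)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$covariance %*% fit$precision - diag(6))), 1e-4)
})

test_that("log likelihood follows the determinant/trace formula", {
  expect_equal(log_likelihood(diag(2), diag(2), 10), -10)
  S <- random_corr(4, seed = 3)
  theta <- solve(S)
  expect_equal(log_likelihood(theta, S, 20),
               (20 / 2) * (log(det(solve(S))) - 4))
  set.seed(5)
  A <- crossprod(matrix(rnorm(16), 4))
  theta2 <- A / mean(diag(A))
  expect_equal(log_likelihood(theta2, S, 17),
               (17 / 2) * (determinant(theta2)$modulus[[1]] -
                             sum(diag(S %*% theta2))))
  expect_error(log_likelihood(-diag(4), S, 10), "positive definite")
})

test_that("ebic reduces to BIC at gamma 0 and is additive in edge count", {
  S <- random_corr(5, seed = 21)
  fit <- glasso_fit(S, 0.05)
  th <- fit$precision
  n <- 40
  E <- sum(th[upper.tri(th)] != 0)
  expect_equal(ebic(th, S, n, gamma = 0),
               -2 * log_likelihood(th, S, n) + E * log(n))
  # hand evaluation of the full formula
  expect_equal(ebic(th, S, n, gamma = 0.5),
               -2 * log_likelihood(th, S, n) + E * log(n) +
                 4 * E * 0.5 * log(5))
  expect_error(ebic(th, S, n, gamma = -1), "nonnegative")
})

test_that("lambda_path is log-spaced with exact endpoints", {
  S <- matrix(c(1, 0.8, 0.8, 1), 2)
  expect_equal(lambda_path(S, m = 2, ratio = 0.1), c(0.8, 0.08))
  S <- random_corr(6, seed = 2)
  path <- lambda_path(S, m = 100, ratio = 0.01)
  expect_equal(length(path), 100)
  expect_true(all(diff(path) < 0))
  ratios <- path[-1] / path[-length(path)]
  expect_lt(diff(range(ratios)), 1e-10)
  expect_equal(path[1], max(abs(S[upper.tri(S)])))
  # the first penalty yields the empty network
  fit <- glasso_fit(S, path[1])
  expect_true(all(fit$precision[upper.tri(fit$precision)] == 0))
  expect_warning(p0 <- lambda_path(diag(3)), "zero")
  expect_equal(p0, 0)
})

test_that("precision_to_partial applies the sign-flipped scaling", {
  expect_equal(precision_to_partial(diag(c(2, 3, 4))), matrix(0, 3, 3))
  th <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(precision_to_partial(th)[1, 2], 0.5)
  # negative precision entry -> positive partial correlation
  S <- random_corr(4, seed = 6)
  th <- solve(S)
  P <- precision_to_partial(th)
  off <- which(upper.tri(th) & th != 0, arr.ind = TRUE)
  expect_true(all(sign(P[off]) == -sign(th[off])))
  expect_true(all(abs(P[upper.tri(P)]) < 1))
  expect_equal(diag(P), rep(0, 4))
  expect_error(precision_to_partial(matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("ebic selection is sparser at higher gamma and records the path", {
  corpus <- simulate_corpus(generator_spec(p = 6, n_days = 200,
                                           mean_daily_posts = 500, seed = 31))
  S <- correlation_matrix(corpus$series)
  net0 <- ebic_glasso_select(S, gamma = 0, threshold = FALSE)
  net5 <- ebic_glasso_select(S, gamma = 0.5, threshold = FALSE)
  E <- function(net) sum(net$partial[upper.tri(net$partial)] != 0)
  expect_lte(E(net5), E(net0))
  # selected penalty minimizes the recorded EBIC curve
  expect_equal(net5$lam_selected,
               net5$path$lambda[which.min(net5$path$ebic)])
  # sparsity grows as the penalty relaxes; the exact glasso path allows an
  # occasional single edge to leave the active set, so the trend is checked
  # rather than strict monotonicity
  e <- net5$path$edges
  expect_equal(e[1], 0)
  expect_true(all(diff(e) >= -1))
  expect_gt(cor(seq_along(e), e, method = "spearman"), 0.9)
})

test_that("variable permutation permutes the estimated network identically", {
  truth <- make_partial_corr_model(generator_spec(p = 6, seed = 17))
  z <- latent_draws(truth, 300, seed = 18)
  perm <- c(4, 1, 6, 2, 5, 3)
  net1 <- ebic_glasso_select(correlation_matrix(z))
  net2 <- ebic_glasso_select(correlation_matrix(z[, perm]))
  expect_equal(unname(net2$partial), unname(net1$partial[perm, perm]),
               tolerance = 1e-6)
})

test_that("sub-threshold edges are removed only when thresholding is on", {
  truth <- make_partial_corr_model(generator_spec(seed = 23))
  z <- latent_draws(truth, 1000, seed = 24)
  S <- correlation_matrix(z)
  raw <- ebic_glasso_select(S, threshold = FALSE)
  thr <- ebic_glasso_select(S, threshold = TRUE)
  expect_equal(thr$threshold, sqrt(log(11 * 10 / 2) / 1000))
  kept <- abs(raw$partial) >= thr$threshold
  expect_equal(thr$partial[kept], raw$partial[kept])
  expect_true(all(thr$partial[!kept] == 0))
})
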