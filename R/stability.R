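# Shared helper: observations matrix from a topic_series or plain matrix.
obs_matrix <- function(series) {
  x <- if (inherits(series, "topic_series")) series$proportions else as.matrix(series)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}

fit_network <- function(x, method, gamma, m, ratio, threshold = TRUE) {
  S <- correlation_matrix(x, method = method)
  ebic_glasso_select(S, gamma = gamma, m = m, ratio = ratio,
                     threshold = threshold)
}

stat_vector <- function(net, statistic, alpha) {
  if (is.function(statistic)) return(statistic(net, alpha))
  switch(statistic,
    edge = upper_tri_values(net$partial),
    strength = as.numeric(strength(net)),
    closeness = as.numeric(closeness(net, alpha)),
    betweenness = as.numeric(betweenness(net, alpha)),
    stopf("unknown statistic '%s'", statistic)
  )
}

#' Nonparametric bootstrap of network edge weights
#'
#' Resamples days (rows of the series) with replacement, re-runs the full
#' correlation + EBIC-glasso pipeline on each replicate, and records every
#' upper-triangle edge weight — including edges that are zero in the
#' full-sample network, so their sampling variability is tracked too.
#' Replicates whose estimation fails (e.g. a degenerate resample) are dropped
#' and counted; more than 10% failures aborts.
#'
#' @param series a [topic_series()] or numeric matrix (rows = days).
#' @param B number of bootstrap replicates (default 1000).
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param method correlation method (default `"nonparanormal"`).
#' @param m,ratio penalty-path parameters (see [lambda_path()]).
#' @param threshold drop sub-threshold edges from every estimated network
#'   (see [ebic_glasso_select()]; default TRUE).
#' @param seed integer seed; all resampling derives from it.
#' @return object of class `bootstrap_result`: list with `B` (requested),
#'   `B_effective` (successful), `replicates` (B_effective x n_pairs matrix),
#'   `full` (full-sample edge vector), `ci` (per-edge 2.5/97.5 percentile
#'   bounds and replicate median), `topics`, `gamma`, `seed`.
#' @export
bootstrap_edges <- function(series, B = 1000, gamma = 0.5,
                            method = "nonparanormal", m = 100, ratio = 0.01,
                            threshold = TRUE, seed = 1L) {
  if (B < 2) stopf("B must be at least 2")
  x <- obs_matrix(series)
  n <- nrow(x)
  full_net <- fit_network(x, method, gamma, m, ratio, threshold)
  labels <- upper_tri_labels(full_net$topics)
  full_vec <- upper_tri_values(full_net$partial)

  seeds <- split_seed(seed, B)
  reps <- matrix(NA_real_, B, length(labels), dimnames = list(NULL, labels))
  fail <- 0L
  for (b in seq_len(B)) {
    idx <- with_seed(seeds[b], sample.int(n, n, replace = TRUE))
    fit <- tryCatch(
      suppressWarnings(fit_network(x[idx, , drop = FALSE], method, gamma, m, ratio, threshold)),
      error = function(e) NULL)
    if (is.null(fit)) { fail <- fail + 1L; next }
    reps[b, ] <- upper_tri_values(fit$partial)
  }
  if (fail > 0.10 * B)
    stopf("%d of %d bootstrap replicates failed (> 10%%)", fail, B)
  reps <- reps[!is.na(reps[, 1]), , drop = FALSE]
  ci <- data.frame(
    edge = labels,
    full = full_vec,
    lower = apply(reps, 2, quantile, probs = 0.025, names = FALSE),
    median = apply(reps, 2, quantile, probs = 0.5, names = FALSE),
    upper = apply(reps, 2, quantile, probs = 0.975, names = FALSE),
    stringsAsFactors = FALSE
  )
  structure(list(B = B, B_effective = nrow(reps), failures = fail,
                 replicates = reps, full = stats::setNames(full_vec, labels),
                 ci = ci, topics = full_net$topics, network = full_net,
                 gamma = gamma, method = method, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: B = %d (%d effective, %d failed), %d edge pairs, seed = %d\n",
              x$B, x$B_effective, x$failures, ncol(x$replicates), x$seed))
  invisible(x)
}

#' Bootstrapped edge-weight difference test
#'
#' For every pair of edges (a, b), the difference of their weights across
#' bootstrap replicates is summarized by a percentile interval at the given
#' level; the pair differs significantly when that interval excludes zero.
#' An edge compared with itself is never significant.
#'
#' @param boot a [bootstrap_edges()] result.
#' @param level two-sided test level (default 0.05, i.e. a 95% interval).
#' @return symmetric logical matrix over edges, `FALSE` diagonal; attribute
#'   `level`.
#' @export
edge_difference_test <- function(boot, level = 0.05) {
  if (boot$B_effective < 100)
    warnf("only %d effective replicates; at least 100 recommended",
          boot$B_effective)
  reps <- boot$replicates
  ne <- ncol(reps)
  sig <- matrix(FALSE, ne, ne, dimnames = list(colnames(reps), colnames(reps)))
  probs <- c(level / 2, 1 - level / 2)
  for (a in seq_len(ne - 1)) {
    d <- reps[, (a + 1):ne, drop = FALSE] - reps[, a]
    qs <- apply(d, 2, quantile, probs = probs, names = FALSE)
    hit <- qs[1, ] > 0 | qs[2, ] < 0
    sig[a, (a + 1):ne] <- hit
    sig[(a + 1):ne, a] <- hit
  }
  attr(sig, "level") <- level
  sig
}

#' Case-drop subsampling CS coefficient
#'
#' Measures how much of the data can be discarded while the chosen network
#' statistic stays essentially the same. For each drop proportion q in
#' `drop_grid`, `B` subsamples of ceiling((1-q)·n) days are drawn without
#' replacement, the pipeline is re-estimated, and the Pearson correlation
#' between the subsample statistic vector and the full-sample vector is
#' recorded. The CS coefficient is the largest q such that at least
#' `certainty` (default 95%) of the correlations reach `corr_threshold`
#' (default 0.7) at q and at every smaller grid point; 0 if none qualifies.
#' Values above 0.5 indicate good stability; 0.25 is the minimum acceptable.
#'
#' @param series a [topic_series()] or numeric matrix (rows = days).
#' @param statistic one of `"edge"`, `"strength"`, `"closeness"`,
#'   `"betweenness"`, or a function `f(net, alpha)` returning a numeric
#'   vector for a fitted network (reported as `"custom"`).
#' @param drop_grid drop proportions in (0, 0.9) (default 0.05..0.75 by 0.05).
#' @param B subsamples per grid point (default 250).
#' @param corr_threshold,certainty CS thresholds (defaults 0.7 and 0.95).
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param alpha centrality tuning parameter (default 1).
#' @param method correlation method (default `"nonparanormal"`).
#' @param m,ratio penalty-path parameters.
#' @param threshold drop sub-threshold edges from every estimated network
#'   (see [ebic_glasso_select()]; default TRUE).
#' @param seed integer seed.
#' @return object of class `cs_result`: list with `statistic`, `cs`,
#'   `drop_grid`, `prop_ok` (qualifying fraction per grid point),
#'   `correlations` (list of per-grid correlation samples), thresholds and
#'   `seed`.
#' @export
case_drop_cs <- function(series, statistic = "edge",
                         drop_grid = seq(0.05, 0.75, by = 0.05), B = 250,
                         corr_threshold = 0.7, certainty = 0.95, gamma = 0.5,
                         alpha = 1, method = "nonparanormal", m = 100,
                         ratio = 0.01, threshold = TRUE, seed = 1L) {
  if (any(drop_grid <= 0 | drop_grid >= 0.9))
    stopf("drop_grid proportions must lie in (0, 0.9)")
  if (B < 50) stopf("B must be at least 50")
  drop_grid <- sort(drop_grid)
  x <- obs_matrix(series)
  n <- nrow(x)
  full_net <- fit_network(x, method, gamma, m, ratio, threshold)
  stat_name <- if (is.function(statistic)) "custom" else statistic
  full_vec <- stat_vector(full_net, statistic, alpha)
  if (sd(full_vec) == 0)
    stopf("full-sample %s vector is constant; stability correlation undefined",
          stat_name)

  seeds <- split_seed(seed, length(drop_grid) * B)
  dim(seeds) <- c(length(drop_grid), B)
  cors <- vector("list", length(drop_grid))
  names(cors) <- as.character(drop_grid)
  for (gi in seq_along(drop_grid)) {
    q <- drop_grid[gi]
    keep <- ceiling((1 - q) * n)
    if (keep < 3) { cors[[gi]] <- rep(NA_real_, B); next }
    cc <- numeric(B)
    for (b in seq_len(B)) {
      idx <- with_seed(seeds[gi, b], sample.int(n, keep, replace = FALSE))
      fit <- tryCatch(
        suppressWarnings(fit_network(x[idx, , drop = FALSE], method, gamma, m, ratio, threshold)),
        error = function(e) NULL)
      if (is.null(fit)) { cc[b] <- NA_real_; next }
      v <- stat_vector(fit, statistic, alpha)
      cc[b] <- if (sd(v) == 0) NA_real_ else cor(v, full_vec)
    }
    cors[[gi]] <- cc
  }
  # fraction qualifying; failed / degenerate subsamples never qualify
  prop_ok <- vapply(cors, function(cc) mean(!is.na(cc) & cc >= corr_threshold),
                    numeric(1))
  ok <- prop_ok >= certainty
  cs <- 0
  for (gi in seq_along(drop_grid)) {
    if (!ok[gi]) break
    cs <- drop_grid[gi]
  }
  structure(list(statistic = stat_name, cs = cs, drop_grid = drop_grid,
                 prop_ok = as.numeric(prop_ok), correlations = cors,
                 corr_threshold = corr_threshold, certainty = certainty,
                 B = B, n = n, seed = seed),
            class = "cs_result")
}

#' @export
print.cs_result <- function(x, ...) {
  cat(sprintf("cs_result (%s): CS = %.2f (corr >= %.2f with %.0f%% certainty), n = %d, B = %d\n",
              x$statistic, x$cs, x$corr_threshold, 100 * x$certainty, x$n, x$B))
  invisible(x)
}

#' Write a bootstrap stability report as JSON
#'
#' Serializes seed, replicate counts, per-edge confidence-interval table, the
#' edge-difference matrix and any CS summaries into one machine-readable
#' report.
#'
#' @param boot a [bootstrap_edges()] result.
#' @param diff matrix from [edge_difference_test()] (optional).
#' @param cs_list list of [case_drop_cs()] results (optional).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stability_json <- function(boot, diff = NULL, cs_list = NULL, path) {
  obj <- list(
    seed = boot$seed, B = boot$B, B_effective = boot$B_effective,
    failures = boot$failures, gamma = boot$gamma, method = boot$method,
    edge_ci = boot$ci
  )
  if (!is.null(diff))
    obj$difference_test <- list(level = attr(diff, "level"),
                                edges = colnames(diff),
                                significant = unclass(diff))
  if (!is.null(cs_list))
    obj$cs <- lapply(cs_list, function(r)
      list(statistic = r$statistic, cs = r$cs, drop_grid = r$drop_grid,
           prop_ok = r$prop_ok, corr_threshold = r$corr_threshold,
           certainty = r$certainty, B = r$B, n = r$n, seed = r$seed))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", dataframe = "columns")
  invisible(path)
}
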