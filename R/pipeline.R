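#' Analysis configuration
#'
#' Collects every tunable of the full pipeline in one serializable object;
#' a config plus its seed reproduces all outputs exactly. Fields not supplied
#' keep the documented defaults, and the complete config (no hidden defaults)
#' is echoed into every run's output directory.
#'
#' @param posts path to a posts CSV/TSV (see [read_posts()]); alternatively
#'   supply `series`.
#' @param series a [topic_series()] object (takes precedence over `posts`).
#' @param topic_set admissible topic codes.
#' @param date_range optional pair of dates passed to
#'   [build_daily_proportions()].
#' @param method correlation method.
#' @param gamma EBIC hyperparameter.
#' @param alpha centrality tuning parameter.
#' @param B_boot edge-bootstrap replicates (default 1000).
#' @param B_cs case-drop subsamples per grid point (default 250).
#' @param drop_grid case-drop proportions.
#' @param level edge-difference test level.
#' @param cs_statistics statistics for which to compute CS coefficients.
#' @param m,ratio penalty-path parameters.
#' @param threshold drop sub-threshold edges from every estimated network
#'   (see [ebic_glasso_select()]).
#' @param seed master seed for all randomness.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(posts = NULL, series = NULL,
                            topic_set = default_topic_set()$code,
                            date_range = NULL, method = "nonparanormal",
                            gamma = 0.5, alpha = 1, B_boot = 1000,
                            B_cs = 250, drop_grid = seq(0.05, 0.75, by = 0.05),
                            level = 0.05, cs_statistics = "edge", m = 100,
                            ratio = 0.01, threshold = TRUE, seed = 1L) {
  if (is.null(posts) && is.null(series))
    stopf("supply either a posts file path or a topic_series")
  structure(list(posts = posts, series = series, topic_set = topic_set,
                 date_range = date_range, method = method, gamma = gamma,
                 alpha = alpha, B_boot = B_boot, B_cs = B_cs,
                 drop_grid = drop_grid, level = level,
                 cs_statistics = cs_statistics, m = m, ratio = ratio,
                 threshold = threshold, seed = as.integer(seed)),
            class = "analysis_config")
}

config_echo <- function(config) {
  out <- unclass(config)
  out$series <- if (is.null(config$series)) NULL else "<in-memory topic_series>"
  out$date_range <- if (is.null(config$date_range)) NULL else
    as.character(config$date_range)
  out
}

#' Run the full topic-network analysis
#'
#' Executes ingest, correlation, EBIC-glasso network estimation, centrality
#' and clustering, edge bootstrap with difference test, and case-drop CS
#' estimation, writing all report artifacts into `out_dir`:
#' \itemize{
#'   \item `edges.tsv` — nonzero partial-correlation edge list
#'   \item `network.json` — full matrix, penalty path, EBIC curve, seed
#'   \item `centrality.csv` — strength/closeness/betweenness/clustering and
#'     z-scores
#'   \item `clustering_vs_centrality.csv` — per-topic clustering against the
#'     centrality z-scores (peripherality diagnostics)
#'   \item `stability.json` — edge CIs, difference-test matrix, CS summaries
#'   \item `config.json` — complete config echo
#'   \item `run.log` — versions, seed, warning counts (the only
#'     non-deterministic artifact)
#' }
#' JSON/CSV payloads are byte-identical across reruns with the same config.
#' On any stage failure, partially written outputs are removed and the error
#' is re-raised with the stage name.
#'
#' @param config an [analysis_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `series`, `correlation`, `network`,
#'   `centrality`, `bootstrap`, `difference`, `cs`, and `files`.
#' @export
run_analysis <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(out_dir, c("edges.tsv", "network.json", "centrality.csv",
                                "clustering_vs_centrality.csv",
                                "stability.json", "config.json", "run.log"))
  names(files) <- c("edges", "network", "centrality", "clustvcent",
                    "stability", "config", "log")
  n_warn <- 0L
  stage <- function(name, expr) {
    tryCatch(
      withCallingHandlers(expr, warning = function(w) {
        n_warn <<- n_warn + 1L
        message(sprintf("[%s] warning: %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        unlink(files)
        stopf("stage '%s' failed: %s", name, conditionMessage(e))
      })
  }

  series <- stage("ingest", {
    if (!is.null(config$series)) config$series
    else build_daily_proportions(read_posts(config$posts, config$topic_set),
                                 config$topic_set, config$date_range)
  })
  R <- stage("correlation", correlation_matrix(series, config$method))
  net <- stage("ggm", ebic_glasso_select(R, gamma = config$gamma,
                                         m = config$m, ratio = config$ratio,
                                         threshold = config$threshold))
  cent <- stage("netmetrics", centrality_table(net, alpha = config$alpha))
  seeds <- split_seed(config$seed, 1 + length(config$cs_statistics))
  boot <- stage("stability", bootstrap_edges(series, B = config$B_boot,
                                             gamma = config$gamma,
                                             method = config$method,
                                             m = config$m,
                                             ratio = config$ratio,
                                             threshold = config$threshold,
                                             seed = seeds[1]))
  diff <- stage("stability", edge_difference_test(boot, level = config$level))
  cs_list <- stage("stability", {
    out <- list()
    for (k in seq_along(config$cs_statistics)) {
      # a sparse full-sample network can make a statistic vector constant
      # (e.g. no edges at all); report no CS for it rather than aborting
      r <- tryCatch(
        case_drop_cs(series, statistic = config$cs_statistics[k],
                     drop_grid = config$drop_grid, B = config$B_cs,
                     gamma = config$gamma, alpha = config$alpha,
                     method = config$method, m = config$m,
                     ratio = config$ratio, threshold = config$threshold,
                     seed = seeds[1 + k]),
        error = function(e) {
          warnf("CS for statistic '%s' unavailable: %s",
                config$cs_statistics[k], conditionMessage(e))
          NULL
        })
      if (!is.null(r)) out[[config$cs_statistics[k]]] <- r
    }
    out
  })

  stage("report", {
    write_edge_list(net, files["edges"])
    write_network_json(net, files["network"], seed = config$seed)
    write_centrality_table(cent, files["centrality"])
    cvc <- cent[, c("topic", "clustering", "strength_z", "closeness_z",
                    "betweenness_z")]
    cvc$mean_centrality_z <- rowMeans(cvc[, c("strength_z", "closeness_z",
                                              "betweenness_z")])
    write.csv(cvc, files["clustvcent"], row.names = FALSE)
    write_stability_json(boot, diff, cs_list, files["stability"])
    jsonlite::write_json(config_echo(config), files["config"], digits = NA,
                         auto_unbox = TRUE, null = "null")
    log_lines <- c(
      sprintf("sentinet %s on %s", as.character(utils::packageVersion("sentinet")),
              R.version.string),
      sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
      sprintf("seed %d", config$seed),
      sprintf("days %d, topics %d, posts %s", length(series$dates),
              length(series$topics), format(sum(series$counts))),
      sprintf("selected lambda %.6g, edges %d", net$lam_selected,
              sum(net$partial[upper.tri(net$partial)] != 0)),
      sprintf("bootstrap failures %d of %d", boot$failures, boot$B),
      sprintf("warnings %d", n_warn)
    )
    writeLines(log_lines, files["log"])
  })

  invisible(list(series = series, correlation = R, network = net,
                 centrality = cent, bootstrap = boot, difference = diff,
                 cs = cs_list, files = files))
}

#' Edge-recovery metrics against a known truth
#'
#' Compares the support and signs of an estimated partial-correlation matrix
#' with the generating one.
#'
#' @param true_partial,est_partial p x p partial-correlation matrices.
#' @return one-row data.frame: `true_edges`, `est_edges`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `sign_accuracy`, `fp_rate` (false positives over
#'   true non-edges). Precision is `NA` when nothing is selected;
#'   `sign_accuracy` is `NA` without true positives.
#' @export
edge_recovery_metrics <- function(true_partial, est_partial) {
  tv <- upper_tri_values(unclass(true_partial))
  ev <- upper_tri_values(unclass(est_partial))
  t_edge <- tv != 0
  e_edge <- ev != 0
  tp <- sum(t_edge & e_edge)
  fp <- sum(!t_edge & e_edge)
  fn <- sum(t_edge & !e_edge)
  data.frame(
    true_edges = sum(t_edge), est_edges = sum(e_edge), tp = tp, fp = fp,
    fn = fn,
    precision = if (sum(e_edge) > 0) tp / sum(e_edge) else NA_real_,
    recall = if (sum(t_edge) > 0) tp / sum(t_edge) else NA_real_,
    sign_accuracy = if (tp > 0)
      mean(sign(tv[t_edge & e_edge]) == sign(ev[t_edge & e_edge]))
    else NA_real_,
    fp_rate = if (sum(!t_edge) > 0) fp / sum(!t_edge) else NA_real_
  )
}

#' Structure-recovery benchmark over replicated synthetic corpora
#'
#' For each replicate, draws a fresh ground truth and data set from `spec`
#' (with a replicate-specific seed derived from `spec$seed`), estimates the
#' network, and scores edge recovery; optionally adds the case-drop CS
#' coefficient of the edge statistic.
#'
#' @param spec a [generator_spec()]; `spec$n_days` is the sample size per
#'   replicate.
#' @param reps number of replicates.
#' @param data `"latent"` scores recovery on the latent Gaussian draws (the
#'   model's natural scale); `"proportions"` runs through the multinomial
#'   observation layer, which attenuates signal at small n.
#' @param gamma,method,m,ratio,threshold estimation controls.
#' @param cs also compute the edge CS coefficient per replicate (costly;
#'   default FALSE).
#' @param B_cs subsamples per grid point when `cs = TRUE`.
#' @return data.frame with one row per replicate plus a final `"mean"` row
#'   aggregating the numeric columns.
#' @export
run_benchmark <- function(spec, reps = 10, data = c("latent", "proportions"),
                          gamma = 0.5, method = "nonparanormal", m = 100,
                          ratio = 0.01, threshold = TRUE, cs = FALSE,
                          B_cs = 100) {
  data <- match.arg(data)
  if (reps < 1) stopf("reps must be at least 1")
  rep_seeds <- split_seed(spec$seed, reps)
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    rspec <- spec
    rspec$seed <- rep_seeds[r]
    corpus <- simulate_corpus(rspec)
    x <- if (data == "latent") corpus$latent else corpus$series$proportions
    net <- fit_network(x, method, gamma, m, ratio, threshold)
    metrics <- edge_recovery_metrics(corpus$truth$true_partial, net$partial)
    metrics$rep <- r
    if (cs) {
      metrics$cs_edge <- case_drop_cs(x, statistic = "edge", B = B_cs,
                                      gamma = gamma, method = method, m = m,
                                      ratio = ratio, threshold = threshold,
                                      seed = rep_seeds[r])$cs
    }
    rows[[r]] <- metrics
  }
  out <- do.call(rbind, rows)
  out <- out[, c("rep", setdiff(names(out), "rep"))]
  agg <- out[1, , drop = FALSE]
  agg$rep <- NA_integer_
  for (cl in setdiff(names(out), "rep"))
    agg[[cl]] <- mean(out[[cl]], na.rm = TRUE)
  rownames(agg) <- "mean"
  rbind(out, agg)
}
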