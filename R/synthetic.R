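#' Specification for the synthetic corpus generator
#'
#' Describes a synthetic social-media corpus: `p` topics observed over
#' `n_days` days, with daily topic proportions driven by a latent Gaussian
#' vector whose precision matrix has a known sparse structure
#' (logistic-normal multinomial model). Defaults emulate a corpus of roughly
#' 68,000 posts across 11 topics over 40 days: `mean_daily_posts = 1700`
#' (about 68,000/40) and unequal baseline topic masses with one dominant
#' topic (for the default 11-topic set, negative emotion P2 dominates and
#' positive emotion P1 is rare).
#'
#' @param p number of topics (default 11).
#' @param n_days number of days (default 40).
#' @param edge_density probability of each upper-triangle edge in the true
#'   precision structure (default 0.2).
#' @param weight_range magnitude range for the generating edge weights
#'   (default c(0.2, 0.4)); signs are random.
#' @param mean_daily_posts Poisson mean of the daily post total (default
#'   1700).
#' @param baseline_logits length-p vector of baseline log-masses; default as
#'   described above.
#' @param topics topic codes; defaults to [default_topic_set()] codes when
#'   p = 11, else `T1..Tp`.
#' @param start_date first calendar day of the series (default
#'   `"2020-01-23"`).
#' @param seed master seed; all generator randomness derives from it.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(p = 11, n_days = 40, edge_density = 0.2,
                           weight_range = c(0.2, 0.4),
                           mean_daily_posts = 1700, baseline_logits = NULL,
                           topics = NULL, start_date = "2020-01-23",
                           seed = 1L) {
  if (p < 2) stopf("need at least 2 topics")
  if (n_days < 1) stopf("need at least 1 day")
  if (edge_density < 0 || edge_density >= 1)
    stopf("edge_density must lie in [0, 1)")
  if (length(weight_range) != 2 || any(weight_range <= 0) ||
      weight_range[1] > weight_range[2])
    stopf("weight_range must be an increasing pair of positive magnitudes")
  if (mean_daily_posts <= 0) stopf("mean_daily_posts must be positive")
  if (is.null(topics))
    topics <- if (p == 11) default_topic_set()$code else paste0("T", seq_len(p))
  if (length(topics) != p) stopf("topics must have length p")
  if (is.null(baseline_logits)) {
    baseline_logits <- if (p == 11) {
      c(G1 = 0.3, G2 = 0.1, G3 = -0.6, G4 = -0.3, G5 = -0.8, G6 = 0,
        P1 = -1.2, P2 = 1.2, M1 = -0.5, M2 = 0.9, M3 = 0.1)
    } else seq(1, -1, length.out = p)
  }
  if (length(baseline_logits) != p) stopf("baseline_logits must have length p")
  structure(list(p = p, n_days = n_days, edge_density = edge_density,
                 weight_range = weight_range,
                 mean_daily_posts = mean_daily_posts,
                 baseline_logits = as.numeric(baseline_logits),
                 topics = topics, start_date = as.Date(start_date),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Draw a sparse partial-correlation ground truth
#'
#' Builds the true precision matrix: upper-triangle edges are present
#' independently with probability `edge_density`, with magnitudes uniform in
#' `weight_range` and random sign; the precision is assembled as I minus the
#' symmetric edge matrix, diagonally loaded (in steps of 0.1, at most 50
#' times) until its smallest eigenvalue reaches 0.05, and rescaled to unit
#' diagonal. The implied covariance is its inverse, rescaled to a correlation
#' matrix.
#'
#' @param spec a [generator_spec()].
#' @return object of class `ground_truth`: list with `precision`,
#'   `true_partial` (via [precision_to_partial()]), `true_covariance`
#'   (correlation-scaled), `topics`.
#' @export
make_partial_corr_model <- function(spec) {
  p <- spec$p
  seeds <- split_seed(spec$seed, 3)
  A <- with_seed(seeds[1], {
    A <- matrix(0, p, p)
    up <- which(upper.tri(A))
    present <- runif(length(up)) < spec$edge_density
    mag <- runif(length(up), spec$weight_range[1], spec$weight_range[2])
    sgn <- sample(c(-1, 1), length(up), replace = TRUE)
    A[up] <- present * mag * sgn
    A + t(A)
  })
  K <- diag(p) - A
  tries <- 0
  while (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) < 0.05) {
    tries <- tries + 1
    if (tries > 50)
      stopf("cannot reach positive definiteness within 50 diagonal loadings; spec infeasible")
    K <- K + 0.1 * diag(p)
  }
  K <- stats::cov2cor(K)
  Sigma <- stats::cov2cor(solve(K))
  dimnames(K) <- dimnames(Sigma) <- list(spec$topics, spec$topics)
  structure(list(precision = K, true_partial = precision_to_partial(K),
                 true_covariance = Sigma, topics = spec$topics),
            class = "ground_truth")
}

#' Simulate a daily topic series from a ground truth
#'
#' Per day t, a latent Gaussian vector z_t ~ N(0, Sigma) is drawn, mapped to
#' topic probabilities by a softmax over `baseline_logits + z_t`, the daily
#' post total is Poisson(`mean_daily_posts`) (redrawn if zero), and per-topic
#' counts are multinomial. The result is assembled through the same
#' constructor as real ingested data.
#'
#' @param truth a [make_partial_corr_model()] result.
#' @param spec the matching [generator_spec()].
#' @return list with `series` (a [topic_series()]) and `latent` (the n x p
#'   matrix of latent Gaussian draws, the recovery target's natural scale).
#' @export
simulate_topic_series <- function(truth, spec) {
  p <- spec$p
  n <- spec$n_days
  seeds <- split_seed(spec$seed, 3)
  R <- chol(truth$true_covariance)
  z <- with_seed(seeds[2], matrix(rnorm(n * p), n, p) %*% R)
  colnames(z) <- spec$topics
  counts <- with_seed(seeds[3], {
    cts <- matrix(0L, n, p)
    for (t in seq_len(n)) {
      tot <- 0L
      while (tot == 0L) tot <- rpois(1, spec$mean_daily_posts)
      pi_t <- softmax(spec$baseline_logits + z[t, ])
      cts[t, ] <- as.integer(rmultinom(1, tot, pi_t))
    }
    cts
  })
  dates <- spec$start_date + seq_len(n) - 1
  dimnames(counts) <- list(as.character(dates), spec$topics)
  list(series = topic_series(counts), latent = z)
}

#' Expand a topic series back into individual post records
#'
#' Inverse of [build_daily_proportions()]: each (day, topic) count cell is
#' expanded into that many post records with synthetic ids, shuffled
#' deterministically by `seed`. Useful for round-trip testing of ingestion.
#'
#' @param series a [topic_series()].
#' @param seed shuffle seed.
#' @return data.frame of post records (`date`, `topic`, `id`).
#' @export
expand_posts <- function(series, seed = 1L) {
  cells <- which(series$counts > 0, arr.ind = TRUE)
  date <- rep(as.character(series$dates)[cells[, 1]],
              series$counts[cells])
  topic <- rep(series$topics[cells[, 2]], series$counts[cells])
  n <- length(date)
  ord <- with_seed(seed, sample.int(n))
  data.frame(date = as.Date(date[ord]), topic = topic[ord],
             id = sprintf("post-%07d", seq_len(n)),
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic corpus
#'
#' Convenience wrapper drawing the ground truth, the topic series and the
#' expanded post records in one call.
#'
#' @param spec a [generator_spec()].
#' @return list with `spec`, `truth`, `series`, `latent`, `posts`.
#' @export
#' @examples
#' corpus <- simulate_corpus(generator_spec(p = 4, n_days = 10,
#'                                          mean_daily_posts = 50, seed = 7))
#' corpus$series
simulate_corpus <- function(spec) {
  truth <- make_partial_corr_model(spec)
  sim <- simulate_topic_series(truth, spec)
  posts <- expand_posts(sim$series, seed = split_seed(spec$seed, 4)[4])
  list(spec = spec, truth = truth, series = sim$series, latent = sim$latent,
       posts = posts)
}

#' Write the generator's ground truth as JSON
#'
#' Records the true partial-correlation matrix alongside an echo of the
#' generator specification, for later recovery scoring.
#'
#' @param truth a `ground_truth`.
#' @param spec the matching `generator_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, spec, path) {
  obj <- list(
    topics = truth$topics,
    true_partial = unclass(truth$true_partial),
    spec = list(p = spec$p, n_days = spec$n_days,
                edge_density = spec$edge_density,
                weight_range = spec$weight_range,
                mean_daily_posts = spec$mean_daily_posts,
                baseline_logits = spec$baseline_logits,
                topics = spec$topics,
                start_date = as.character(spec$start_date),
                seed = spec$seed)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
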