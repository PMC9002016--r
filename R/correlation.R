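#' Rank-based inverse normal transform
#'
#' Maps a numeric vector to normal scores y_i = qnorm((r_i - 0.5)/n), where
#' r_i is the (tie-averaged) rank of x_i. The transform is invariant to
#' monotone transformations of the input and gives each variable an
#' approximately standard-normal marginal, which is the usual preprocessing
#' before Gaussian graphical model estimation when raw variables (here, daily
#' topic proportions) are continuous but not normal.
#'
#' @param x numeric vector, length >= 3, not all values identical.
#' @return numeric vector of normal scores, same length as `x`.
#' @export
#' @examples
#' rank_inverse_normal(c(10, 20, 30))  # middle value maps exactly to 0
rank_inverse_normal <- function(x) {
  if (length(x) < 3) stopf("need at least 3 observations")
  if (anyNA(x)) stopf("missing values not allowed")
  if (diff(range(x)) == 0)
    stopf("constant vector: rank-based transform undefined")
  r <- rank(x, ties.method = "average")
  qnorm((r - 0.5) / length(x))
}

#' Repair a symmetric matrix to positive semidefiniteness
#'
#' Clips eigenvalues below at 1e-8, reconstitutes the matrix, and rescales to
#' unit diagonal. A matrix that is already positive definite is returned
#' unchanged. With few observations per variable (e.g. 40 days for 11 topics)
#' an empirical correlation matrix can be near-singular; the graphical lasso
#' requires at least PSD input.
#'
#' @param S symmetric matrix.
#' @param eig_floor smallest admissible eigenvalue (default 1e-8).
#' @return symmetric positive-definite matrix with unit diagonal.
#' @export
nearest_pd_repair <- function(S, eig_floor = 1e-8) {
  if (!is_square_symmetric(S))
    stopf("input is not symmetric (tolerance 1e-10)")
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= eig_floor) return(S)
  vals <- pmax(e$values, eig_floor)
  R <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  diag(R) <- 1
  (R + t(R)) / 2
}

#' Correlation matrix of a topic series
#'
#' Computes the p x p correlation matrix of the daily proportion columns that
#' is the input to [ebic_glasso_select()]. The default `nonparanormal` method
#' applies [rank_inverse_normal()] to each column before taking Pearson
#' correlations, accommodating non-normal marginals; `pearson` and `spearman`
#' are available as alternatives. The result is passed through
#' [nearest_pd_repair()].
#'
#' @param series a [topic_series()] object, or a plain numeric matrix with
#'   column names (columns are variables).
#' @param method one of `"nonparanormal"` (default), `"pearson"`,
#'   `"spearman"`.
#' @return object of class `correlation_matrix`: the p x p matrix with
#'   attributes `method` and `n` (number of rows used).
#' @export
correlation_matrix <- function(series, method = c("nonparanormal", "pearson",
                                                  "spearman")) {
  method <- match.arg(method)
  x <- if (inherits(series, "topic_series")) series$proportions else as.matrix(series)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (nrow(x) < 3) stopf("need at least 3 observations (days)")
  const <- apply(x, 2, function(v) diff(range(v)) == 0)
  if (any(const))
    stopf("constant column(s): %s", paste(colnames(x)[const], collapse = ", "))
  R <- switch(method,
    pearson = cor(x, method = "pearson"),
    spearman = cor(x, method = "spearman"),
    nonparanormal = cor(apply(x, 2, rank_inverse_normal), method = "pearson")
  )
  R <- nearest_pd_repair(R)
  dimnames(R) <- list(colnames(x), colnames(x))
  structure(R, method = method, n = nrow(x), class = c("correlation_matrix",
                                                       "matrix", "array"))
}

#' Write a correlation matrix as a square CSV
#'
#' @param R correlation matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(R, path) {
  df <- data.frame(topic = rownames(R), unclass(R), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
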