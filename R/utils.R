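#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state so
#' package functions never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a stream of component seeds from one master seed
#'
#' All randomness in a multi-stage run flows from a single seed: the master
#' seed initializes the RNG once and `n` independent sub-seeds are drawn from
#' it. Sub-seeds stay below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @keywords internal
#' @noRd
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

upper_tri_values <- function(m) m[upper.tri(m)]

#' Names for the upper-triangle entries of a labelled square matrix
#' @noRd
upper_tri_labels <- function(labels) {
  p <- length(labels)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  paste(labels[idx[, 1]], labels[idx[, 2]], sep = "--")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_square_symmetric <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}
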