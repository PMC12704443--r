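# Internal helpers shared across modules.

#' Centered running mean with partial (valid-window) edges
#'
#' Each output sample is the mean of the input over a centered window of
#' `width` samples; near the edges the window is truncated to the samples
#' that exist, so no padding values are invented.
#'
#' @param x numeric vector.
#' @param width window width in samples (coerced to at least 1).
#' @return numeric vector of the same length as `x`.
#' @keywords internal
running_mean <- function(x, width) {
  width <- max(1L, as.integer(width))
  n <- length(x)
  if (width == 1L || n == 0L) return(x)
  half_lo <- (width - 1L) %/% 2L
  half_hi <- width - 1L - half_lo
  cs <- cumsum(c(0, x))
  idx <- seq_len(n)
  lo <- pmax(idx - half_lo, 1L)
  hi <- pmin(idx + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Numerically stable log-sum-exp
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Draw from a half-Cauchy distribution
#'
#' @param n number of draws.
#' @param scale scale parameter of the underlying Cauchy.
#' @return positive numeric vector.
#' @export
rhalfcauchy <- function(n, scale) {
  abs(rcauchy(n, location = 0, scale = scale))
}

#' Half-Cauchy log-density
#' @keywords internal
dhalfcauchy_log <- function(x, scale) {
  ifelse(x > 0,
         log(2) - log(pi * scale) - log1p((x / scale)^2),
         -Inf)
}

# Run `expr` under a temporary RNG state seeded with `seed`; if `seed` is
# NULL the global RNG stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seeds derived from one master seed (one per modality,
# so adding a modality never perturbs the draws of another).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Sample standard deviation per column of a matrix.
col_sds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt((colSums(m^2) - n * mu^2) / (n - 1))
}
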