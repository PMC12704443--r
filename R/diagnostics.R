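# MCMC convergence diagnostics: split-chain potential scale reduction
# factor (R-hat) and effective sample size.

#' Split-chain R-hat
#'
#' Each chain is split in half, then the classical potential scale
#' reduction factor compares between- and within-chain variance across
#' the split halves.  Values near 1 indicate convergence; the
#' conventional criterion flags parameters at 1.1 or above.
#'
#' @param draws iterations x chains matrix for one parameter.
#' @return scalar R-hat (`NA` for constant draws).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws) %/% 2L
  if (n < 2) return(NA_real_)
  halves <- do.call(cbind, lapply(seq_len(ncol(draws)), function(c)
    cbind(draws[seq_len(n), c], draws[(n + 1L):(2L * n), c])))
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W < 1e-300) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size from combined-chain autocorrelations using the
# initial-positive-sequence rule (sum paired autocorrelations until a
# pair goes negative).
#' Effective sample size across chains
#'
#' @param draws iterations x chains matrix for one parameter.
#' @return scalar ESS estimate.
#' @export
ess_chains <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws); m <- ncol(draws)
  if (n < 4) return(NA_real_)
  W <- mean(apply(draws, 2, var))
  if (W < 1e-300) return(NA_real_)
  B <- if (m > 1) n * var(colMeans(draws)) else 0
  var_plus <- (n - 1) / n * W + B / n
  # chain-averaged autocovariances
  acov <- sapply(seq_len(m), function(c) {
    x <- draws[, c] - mean(draws[, c])
    stats::acf(x, lag.max = min(n - 2L, 200L), plot = FALSE,
               type = "covariance", demean = FALSE)$acf[, 1, 1]
  })
  acov <- rowMeans(acov)
  rho <- 1 - (W - acov[-1]) / var_plus
  # initial positive sequence on paired sums
  s <- 0; k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  ess <- n * m / (1 + 2 * s)
  min(ess, n * m)
}
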