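# A priori power analysis via the noncentral t distribution.

#' Power of a one-sample (or paired) two-tailed t test
#'
#' Exact power from the noncentral t distribution with noncentrality
#' `d * sqrt(n)`.
#'
#' @param n sample size.
#' @param d standardized effect size (Cohen's d).
#' @param sig_level two-tailed alpha.
#' @return power in (0, 1).
#' @export
t_test_power <- function(n, d, sig_level = 0.05) {
  stopifnot(n >= 2)
  crit <- qt(1 - sig_level / 2, df = n - 1)
  ncp <- d * sqrt(n)
  1 - pt(crit, df = n - 1, ncp = ncp) + pt(-crit, df = n - 1, ncp = ncp)
}

#' Required sample size for a two-tailed t test
#'
#' Smallest n whose noncentral-t power reaches the target - the standard
#' a priori power analysis for a within-participant (one-sample or
#' paired) design.  At a medium effect (d = 0.5), alpha = .05 and power
#' .80 this gives n = 34.
#'
#' @param d standardized effect size.
#' @param sig_level two-tailed alpha.
#' @param power target power.
#' @param n_max search bound.
#' @return integer sample size.
#' @export
required_sample_size <- function(d, sig_level = 0.05, power = 0.8,
                                 n_max = 10000) {
  stopifnot(d > 0, power > 0, power < 1)
  for (n in 2:n_max)
    if (t_test_power(n, d, sig_level) >= power) return(n)
  stop("no n up to ", n_max, " reaches the requested power", call. = FALSE)
}
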