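# Bayesian dual-trend state-space change-point model.
#
# Observations Y[n, t] (participant n, time step t, typically a band-power
# course before MW reports) follow participant-level Gaussians around a
# latent level that starts at a participant-specific value and evolves by
# a trend shared across participants.  Two trend series (pre / post)
# govern the evolution: before the discrete change point tau the level
# accumulates the pre-trend increments; from tau onward it accumulates
# the post-trend increments, starting from the value the pre series has
# reached at the change point - so the latent course is continuous and
# tau marks a trend break.  The trends are Gaussian random walks with
# half-Cauchy(0, 2.5) innovation scales; observation noise is
# per-participant half-Cauchy(0, 5).  tau is uniform over interior
# steps; its posterior is recovered from the per-candidate conditional
# log-likelihoods (Rao-Blackwellized mass), and the log-sum-exp marginal
# likelihood over tau is exposed for cross-checks against brute-force
# per-candidate fits.

#' Assemble a change-point data object
#'
#' @param Y participant x time-step matrix of band power, no missing
#'   values, at least 10 steps.
#' @param step_dt step size in seconds.
#' @param t0_offset seconds before the report corresponding to step 0
#'   (one step before the first column), so that step k maps to
#'   `t0_offset - k * step_dt` seconds before the report.
#' @return object of class `cp_data`.
#' @export
cp_data <- function(Y, step_dt = 0.1, t0_offset = ncol(Y) * step_dt + 0.5) {
  Y <- as.matrix(Y)
  if (anyNA(Y)) stop("Y must not contain missing values", call. = FALSE)
  if (ncol(Y) < 10) stop("need at least 10 time steps", call. = FALSE)
  structure(list(Y = Y, step_dt = step_dt, t0_offset = t0_offset),
            class = "cp_data")
}

#' Build a pre-report power matrix from per-participant courses
#'
#' Stacks the outputs of [prereport_power_course()] into a `cp_data`
#' object, carrying the time grid over so change-point steps convert
#' back to seconds before the report.  By default each participant's
#' course is expressed in relative power (divided by its own mean), the
#' usual normalization that puts band power from different heads on a
#' common scale - and the scale the model's fixed half-Cauchy priors
#' expect.
#'
#' @param courses list of non-NULL course vectors (same grid).
#' @param normalize divide each course by its mean.
#' @return a `cp_data`.
#' @export
cp_data_from_courses <- function(courses, normalize = TRUE) {
  courses <- courses[!vapply(courses, is.null, TRUE)]
  if (!length(courses)) stop("no usable courses", call. = FALSE)
  tb <- attr(courses[[1]], "times_before")
  Y <- do.call(rbind, lapply(courses, as.numeric))
  if (normalize) Y <- Y / rowMeans(Y)
  step_dt <- abs(tb[2] - tb[1])
  cp_data(Y, step_dt = step_dt, t0_offset = tb[1] + step_dt)
}

#' Simulate data from the change-point model at known parameter values
#'
#' Forward-simulates the generative model: shared pre/post trend random
#' walks starting at given slopes, participant levels, and Gaussian
#' observation noise.  The level accumulates pre-trend increments up to
#' the change point and post-trend increments from it (continuous
#' course, trend break at tau).  Setting the innovation scales to zero
#' gives deterministic continuous piecewise-linear rows (the closed-form
#' limit used in tests).
#'
#' @param n participants.
#' @param T_steps time steps.
#' @param tau true change point (1-based step index of the first
#'   post-trend step, interior: 2..T-1).
#' @param slope_pre,slope_post initial trend values (power units per
#'   step).
#' @param sd_delta_pre,sd_delta_post trend innovation scales.
#' @param sd_y observation noise (scalar or per-participant vector).
#' @param mu0 participant initial levels (scalar or vector).
#' @param seed optional seed.
#' @return list with `data` (a `cp_data`) and `truth` (all generating
#'   values).
#' @export
simulate_cp_data <- function(n, T_steps, tau, slope_pre = 0,
                             slope_post = -0.05, sd_delta_pre = 0,
                             sd_delta_post = 0, sd_y = 0.5, mu0 = 5,
                             seed = NULL) {
  stopifnot(tau >= 2, tau <= T_steps - 1)
  with_seed(seed, {
    sy <- rep_len(sd_y, n)
    m0 <- rep_len(mu0, n)
    dpre <- numeric(T_steps - 1); dpost <- numeric(T_steps - 1)
    dpre[1] <- slope_pre; dpost[1] <- slope_post
    for (j in 2:(T_steps - 1)) {
      dpre[j] <- dpre[j - 1] + sd_delta_pre * rnorm(1)
      dpost[j] <- dpost[j - 1] + sd_delta_post * rnorm(1)
    }
    # effective increments: pre up to step tau-2, post from step tau-1
    d_eff <- ifelse(seq_len(T_steps - 1) <= tau - 2, dpre, dpost)
    level <- c(0, cumsum(d_eff))
    Y <- matrix(0, n, T_steps)
    for (i in seq_len(n))
      Y[i, ] <- m0[i] + level + rnorm(T_steps, 0, sy[i])
    list(data = cp_data(Y),
         truth = list(tau = tau, dpre = dpre, dpost = dpost, mu0 = m0,
                      sd_y = sy, sd_delta_pre = sd_delta_pre,
                      sd_delta_post = sd_delta_post))
  })
}

#' Simulate data from the model's prior
#'
#' Draws the scales from their half-Cauchy priors (truncated at
#' `max_scale` so a single heavy-tail draw cannot produce astronomically
#' scaled data), initial trends from their Normal priors, tau uniformly
#' over interior steps, then forward-simulates.
#'
#' @param n,T_steps problem size.
#' @param seed optional seed.
#' @param scale_dd,scale_dy prior scales for trend innovations and
#'   observation noise.
#' @param delta1_sd prior SD of the initial trend values.
#' @param max_scale truncation bound for prior scale draws.
#' @return as [simulate_cp_data()].
#' @export
simulate_from_prior <- function(n, T_steps, seed = NULL, scale_dd = 2.5,
                                scale_dy = 5, delta1_sd = 1,
                                max_scale = 20) {
  with_seed(seed, {
    draw_sc <- function(scale) {
      repeat {
        x <- rhalfcauchy(1, scale)
        if (x <= max_scale) return(x)
      }
    }
    tau <- sample(2:(T_steps - 1), 1)
    simulate_cp_data(
      n, T_steps, tau,
      slope_pre = rnorm(1, 0, delta1_sd),
      slope_post = rnorm(1, 0, delta1_sd),
      sd_delta_pre = draw_sc(scale_dd), sd_delta_post = draw_sc(scale_dd),
      sd_y = vapply(seq_len(n), function(i) draw_sc(scale_dy), 1.0),
      mu0 = rnorm(n, 0, 5))
  })
}

#' Per-candidate change-point log-likelihood (reference implementation)
#'
#' Direct evaluation, for each interior candidate tau, of the full data
#' log-likelihood with the level accumulating pre-trend increments up to
#' the change point and post-trend increments from it.  This is the
#' brute-force path the marginalized computation in the sampler must
#' agree with.
#'
#' @param Y data matrix (participants x steps).
#' @param mu1 participant initial levels.
#' @param dpre,dpost trend increment series (length `ncol(Y) - 1`).
#' @param sy per-participant observation noise.
#' @return named numeric vector of log-likelihoods for tau = 2..T-1.
#' @export
cp_tau_loglik <- function(Y, mu1, dpre, dpost, sy) {
  T_steps <- ncol(Y); n <- nrow(Y)
  taus <- 2:(T_steps - 1)
  ll <- vapply(taus, function(tau) {
    d_eff <- ifelse(seq_len(T_steps - 1) <= tau - 2, dpre, dpost)
    level <- c(0, cumsum(d_eff))
    tot <- 0
    for (i in seq_len(n))
      tot <- tot + sum(dnorm(Y[i, ], mu1[i] + level, sy[i], log = TRUE))
    tot
  }, 1.0)
  names(ll) <- taus
  ll
}

#' Marginal log-likelihood over the change point
#'
#' Log-sum-exp of [cp_tau_loglik()] under the uniform interior prior.
#' @inheritParams cp_tau_loglik
#' @return scalar log marginal likelihood.
#' @export
cp_marg_loglik <- function(Y, mu1, dpre, dpost, sy) {
  ll <- cp_tau_loglik(Y, mu1, dpre, dpost, sy)
  logsumexp(ll) - log(length(ll))
}

#' Retained-draw accounting for the MCMC regime
#'
#' With `iter` total iterations per chain of which the first `burnin`
#' are discarded and every `thin`-th retained draw kept:
#' `(iter - burnin) %/% thin` per chain.  The default regime
#' (6000 iterations, 1000 burn-in, thinning 2, 4 chains) retains 2500
#' draws per chain, 10000 in total.
#'
#' @param iter,burnin,thin,chains sampler regime.
#' @return list with `per_chain` and `total`.
#' @export
retained_draws <- function(iter = 6000, burnin = 1000, thin = 2,
                           chains = 4) {
  stopifnot(iter > burnin, thin >= 1, chains >= 1)
  per <- (iter - burnin) %/% thin
  list(per_chain = per, total = per * chains)
}

#' Fit the dual-trend change-point model by MCMC
#'
#' Runs the bundled blocked Gibbs sampler: conditional on the change
#' point and the scales the model is linear-Gaussian, so the levels and
#' both trend series are drawn jointly from their exact multivariate
#' normal conditional; the change point is drawn from its categorical
#' conditional built from the per-candidate log-likelihoods (the same
#' quantities whose log-sum-exp gives the marginalized likelihood, see
#' [cp_marg_loglik()]); the half-Cauchy scale parameters use log-scale
#' random-walk Metropolis steps with burn-in-only adaptation.  Several
#' chains with jittered starting values are run, then split-chain R-hat
#' and effective sample size are computed for every sampled parameter;
#' a warning is issued when any R-hat reaches 1.1, the conventional
#' convergence criterion.
#'
#' @param data a `cp_data`.
#' @param chains,iter,burnin,thin sampler regime (see
#'   [retained_draws()]).
#' @param seed integer seed; chain c uses `seed + c`.
#' @param scale_dd,scale_dy,delta1_sd prior scales.
#' @param mu_sd_mult multiplier on each row's SD for the vague Normal
#'   prior on the participant initial levels.
#' @return object of class `cp_fit`: list with `draws` (chains x
#'   retained x parameters array), `tau` (chains x retained matrix of
#'   sampled change points), `tau_mass` (posterior mass per step),
#'   `diagnostics` (R-hat/ESS per parameter), `data`, `regime`.
#' @export
fit_cp_model <- function(data, chains = 4, iter = 6000, burnin = 1000,
                         thin = 2, seed = 1, scale_dd = 2.5, scale_dy = 5,
                         delta1_sd = 1, mu_sd_mult = 10) {
  stopifnot(inherits(data, "cp_data"))
  Y <- data$Y
  n <- nrow(Y); T_steps <- ncol(Y)
  m0 <- rowMeans(Y)
  rs <- apply(Y, 1, sd)
  rs[rs < 1e-8] <- 1e-8
  s0 <- mu_sd_mult * rs
  # first-difference noise estimate: trend contributes little to
  # step-to-step differences, so sd(diff)/sqrt(2) tracks sigma_y
  sy0 <- apply(Y, 1, function(r) sd(diff(r))) / sqrt(2)
  sy0[sy0 < 1e-8] <- rs[sy0 < 1e-8]
  ret <- retained_draws(iter, burnin, thin, chains)$per_chain
  n_par <- 2 * n + 2 * (T_steps - 1) + 2
  par_names <- c(sprintf("mu1[%d]", seq_len(n)),
                 sprintf("dpre[%d]", seq_len(T_steps - 1)),
                 sprintf("dpost[%d]", seq_len(T_steps - 1)),
                 "sig_dpre", "sig_dpost",
                 sprintf("sig_y[%d]", seq_len(n)))
  draws <- array(NA_real_, c(chains, ret, n_par),
                 dimnames = list(NULL, NULL, par_names))
  tau <- matrix(NA_integer_, chains, ret)
  tau_mass <- numeric(T_steps)
  for (ch in seq_len(chains)) {
    res <- with_seed(seed + ch, {
      jit <- function(x, s) x + rnorm(length(x), 0, s)
      cpp_cp_sampler(Y, iter, burnin, thin,
                     mu1_init = jit(m0, 0.1 * rs),
                     sy_init = sy0 * exp(rnorm(n, 0, 0.2)),
                     sdp_init = 0.05 * exp(rnorm(1, 0, 0.3)),
                     sdq_init = 0.05 * exp(rnorm(1, 0, 0.3)),
                     tau_init = sample(2:(T_steps - 1), 1),
                     m0 = m0, s0 = s0, delta1_sd = delta1_sd,
                     scale_dd = scale_dd, scale_dy = scale_dy)
    })
    draws[ch, , ] <- res$draws
    tau[ch, ] <- res$tau
    tau_mass <- tau_mass + res$tau_prob / chains
  }
  rh <- apply(draws, 3, function(m) split_rhat(t(m)))
  es <- apply(draws, 3, function(m) ess_chains(t(m)))
  if (any(rh >= 1.1, na.rm = TRUE))
    warning("R-hat >= 1.1 for: ",
            paste(par_names[which(rh >= 1.1)], collapse = ", "))
  structure(list(draws = draws, tau = tau, tau_mass = tau_mass,
                 diagnostics = data.frame(parameter = par_names,
                                          rhat = rh, ess = es),
                 data = data,
                 regime = list(chains = chains, iter = iter,
                               burnin = burnin, thin = thin,
                               retained = retained_draws(iter, burnin,
                                                         thin, chains))),
            class = "cp_fit")
}

#' Posterior summary of a change-point fit
#'
#' Reports the change point in steps and in seconds before the report
#' (`seconds = t0_offset - step * step_dt`), both as the posterior mean
#' with a central 95% credible interval and as the posterior mode; the
#' pre- and post-change trend means (each draw averages its trend series
#' on its own side of that draw's change point); and the difference
#' pre - post, whose 95% CI lying entirely above 0 is the "decrease
#' after the change point" verdict.
#'
#' @param fit a `cp_fit`.
#' @return list with `tau` (mean, ci, mode, seconds_before...),
#'   `trend_pre`, `trend_post`, `difference` (mean, ci, decrease), and
#'   `diagnostics` (max R-hat, min ESS).
#' @export
cp_summary <- function(fit) {
  stopifnot(inherits(fit, "cp_fit"))
  dat <- fit$data
  taus <- as.vector(fit$tau)
  n <- sum(grepl("^mu1\\[", dimnames(fit$draws)[[3]]))
  T_steps <- ncol(dat$Y)
  d_idx_pre <- grep("^dpre\\[", dimnames(fit$draws)[[3]])
  d_idx_post <- grep("^dpost\\[", dimnames(fit$draws)[[3]])
  flat <- function(i) as.vector(fit$draws[, , i])
  dpre_m <- sapply(d_idx_pre, flat)     # draws x (T-1)
  dpost_m <- sapply(d_idx_post, flat)
  # trend on each side of that draw's change point: pre increments are
  # active for steps 1..tau-2, post increments from step tau-1 (at
  # tau = 2 there is no active pre step; the first increment stands in)
  pre_mean <- vapply(seq_along(taus), function(k) {
    mean(dpre_m[k, seq_len(max(taus[k] - 2, 1))])
  }, 1.0)
  post_mean <- vapply(seq_along(taus), function(k) {
    mean(dpost_m[k, (taus[k] - 1):(T_steps - 1)])
  }, 1.0)
  diff_draw <- pre_mean - post_mean
  ci <- function(x) unname(quantile(x, c(0.025, 0.975)))
  sec <- function(step) dat$t0_offset - step * dat$step_dt
  mode_tau <- which.max(fit$tau_mass)
  list(
    tau = list(mean = mean(taus), ci = ci(taus), mode = mode_tau,
               seconds_before_mean = sec(mean(taus)),
               seconds_before_ci = rev(sec(ci(taus))),
               seconds_before_mode = sec(mode_tau),
               mass = fit$tau_mass),
    trend_pre = list(mean = mean(pre_mean), ci = ci(pre_mean)),
    trend_post = list(mean = mean(post_mean), ci = ci(post_mean)),
    difference = list(mean = mean(diff_draw), ci = ci(diff_draw),
                      decrease_after_cp = ci(diff_draw)[1] > 0),
    diagnostics = list(max_rhat = max(fit$diagnostics$rhat, na.rm = TRUE),
                       min_ess = min(fit$diagnostics$ess, na.rm = TRUE)))
}

#' @export
print.cp_fit <- function(x, ...) {
  s <- cp_summary(x)
  cat("<cp_fit> ", dim(x$draws)[1], " chains x ", dim(x$draws)[2],
      " draws; change point ", signif(s$tau$seconds_before_mean, 3),
      " s before report (95% CI ",
      paste(signif(s$tau$seconds_before_ci, 3), collapse = " to "),
      "); max R-hat ", signif(s$diagnostics$max_rhat, 4), "\n", sep = "")
  invisible(x)
}
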