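# Dual-trend state-space change-point model: likelihood oracles, draw
# accounting, sampler behavior, and posterior summaries.

test_that("retained-draw accounting matches the default regime", {
  r <- retained_draws(6000, 1000, 2, 4)
  expect_equal(r$per_chain, 2500)
  expect_equal(r$total, 10000)
  expect_equal(retained_draws(1200, 400, 2, 2)$per_chain, 400)
  expect_equal(retained_draws(1001, 1000, 3, 1)$per_chain, 0)
  expect_error(retained_draws(1000, 1000))
})

test_that("marginalized likelihood agrees with brute-force per-tau fits", {
  for (k in 1:5) {
    sim <- simulate_cp_data(3, 15, tau = 8, slope_post = -0.1,
                            sd_y = 0.3, seed = k)
    Y <- sim$data$Y
    set.seed(k)
    mu1 <- rowMeans(Y)
    dpre <- rnorm(14, 0, 0.05); dpost <- rnorm(14, -0.1, 0.05)
    sy <- runif(3, 0.2, 0.5)
    brute <- cp_tau_loglik(Y, mu1, dpre, dpost, sy)
    expected <- max(brute) + log(sum(exp(brute - max(brute)))) - log(13)
    expect_equal(cp_marg_loglik(Y, mu1, dpre, dpost, sy), expected)
    expect_equal(selfcaught:::cpp_cp_marg_loglik(Y, mu1, dpre, dpost, sy),
                 expected, tolerance = 1e-10)
  }
})

test_that("with vanishing innovation the likelihood peaks at the true break", {
  s0 <- simulate_cp_data(4, 30, tau = 12, slope_pre = 0.02,
                         slope_post = -0.1, sd_y = 1e-4, seed = 6)
  ll <- cp_tau_loglik(s0$data$Y, s0$truth$mu0, rep(0.02, 29),
                      rep(-0.1, 29), rep(1e-4, 4))
  expect_equal(names(ll)[which.max(ll)], "12")
})

test_that("equal pre/post trends make the per-tau likelihood exactly flat", {
  sim <- simulate_cp_data(2, 20, tau = 10, slope_pre = 0.05,
                          slope_post = 0.05, sd_y = 0.5, seed = 3)
  d <- rnorm(19, 0, 0.02)
  ll <- cp_tau_loglik(sim$data$Y, sim$truth$mu0, d, d, rep(0.5, 2))
  expect_lt(diff(range(ll)), 1e-9)
})

test_that("prior draws of scales follow the half-Cauchy distribution", {
  set.seed(8)
  x <- rhalfcauchy(10000, 5)
  ks <- suppressWarnings(
    stats::ks.test(x, function(q) 2 / pi * atan(q / 5)))
  expect_gt(ks$p.value, 0.01)
})

test_that("prior simulation is seeded and degenerates to piecewise lines", {
  a <- simulate_from_prior(3, 20, seed = 5)
  b <- simulate_from_prior(3, 20, seed = 5)
  expect_identical(a$data$Y, b$data$Y)
  expect_true(a$truth$tau >= 2 && a$truth$tau <= 19)
  det <- simulate_cp_data(2, 15, tau = 7, slope_pre = 0.1,
                          slope_post = -0.2, sd_delta_pre = 0,
                          sd_delta_post = 0, sd_y = 0, mu0 = 1, seed = 1)
  # second differences vanish except at the break
  for (i in 1:2) {
    d2 <- diff(diff(det$data$Y[i, ]))
    expect_equal(sum(abs(d2) > 1e-12), 1)
  }
})

test_that("the sampler recovers a clear injected change point", {
  d <- simulate_cp_data(10, 50, tau = 20, slope_pre = 0,
                        slope_post = -0.3, sd_y = 0.3, mu0 = 5, seed = 2)
  fit <- suppressWarnings(
    fit_cp_model(d$data, chains = 2, iter = 1200, burnin = 400, thin = 2,
                 seed = 3))
  s <- cp_summary(fit)
  expect_lt(abs(s$tau$mean - 20), 2)
  expect_true(s$difference$decrease_after_cp)
  expect_gt(s$difference$mean, 0)
  # mass sums to one and the retained draw count is honored
  expect_equal(sum(fit$tau_mass), 1, tolerance = 1e-8)
  expect_equal(dim(fit$draws)[2], retained_draws(1200, 400, 2, 2)$per_chain)
  # determinism under the same seed
  fit2 <- suppressWarnings(
    fit_cp_model(d$data, chains = 2, iter = 1200, burnin = 400, thin = 2,
                 seed = 3))
  expect_identical(fit$tau, fit2$tau)
  expect_identical(fit$draws, fit2$draws)
})

test_that("white noise leaves the change point dispersed, not pinned", {
  set.seed(5)
  Y <- matrix(rnorm(3 * 40, 0, 1), 3, 40)
  fit <- suppressWarnings(
    fit_cp_model(cp_data(Y), chains = 2, iter = 1000, burnin = 400,
                 thin = 2, seed = 7))
  tv <- as.vector(fit$tau)
  expect_gt(sd(tv), 2)                  # several steps of spread
  expect_gt(length(unique(tv)), 5)
})

test_that("summaries convert steps to seconds before the report", {
  sim <- simulate_cp_data(4, 60, tau = 30, slope_post = -0.3, sd_y = 0.2,
                          seed = 9)
  dat <- cp_data(sim$data$Y, step_dt = 0.1, t0_offset = 9.4)
  fit <- suppressWarnings(
    fit_cp_model(dat, chains = 2, iter = 800, burnin = 300, thin = 1,
                 seed = 11))
  s <- cp_summary(fit)
  expect_equal(s$tau$seconds_before_mean, 9.4 - s$tau$mean * 0.1)
  expect_equal(s$tau$seconds_before_mode, 9.4 - s$tau$mode * 0.1)
  # the worked conversion: step 47 at 0.1-s steps from offset 9.4 is 4.7 s
  expect_equal(9.4 - 47 * 0.1, 4.7)
})

test_that("diagnostics flag disagreeing chains and accept matching ones", {
  set.seed(15)
  good <- matrix(rnorm(2000), 500, 4)
  expect_lt(split_rhat(good), 1.05)
  bad <- cbind(matrix(rnorm(1000), 500, 2), matrix(rnorm(1000, 5), 500, 2))
  expect_gt(split_rhat(bad), 1.5)
  # autocorrelated draws have a smaller effective sample size
  ar <- matrix(0, 500, 4)
  for (c in 1:4) {
    x <- numeric(500)
    for (i in 2:500) x[i] <- 0.9 * x[i - 1] + rnorm(1)
    ar[, c] <- x
  }
  expect_lt(ess_chains(ar), 0.5 * 2000)
  expect_gt(ess_chains(good), 0.5 * 2000)
})
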