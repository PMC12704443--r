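# Respiration preprocessing, phase detection, channel selection, and the
# resampled-baseline machinery.

test_that("preprocessing removes drift and leaves a sinusoid intact", {
  fs <- 100
  t <- seq(0, 300 - 1 / fs, by = 1 / fs)
  sine <- sin(2 * pi * 0.25 * t)
  # closed-form moving-average gain of a w-point mean at frequency f
  w <- round(0.025 * fs)
  gain <- abs(sin(pi * 0.25 * w / fs) / (w * sin(pi * 0.25 / fs)))
  out <- preprocess_resp(sine, fs)
  mid <- seq(10 * fs, length(t) - 10 * fs)   # away from baseline-window edges
  amp_ratio <- sd(out[mid]) / sd(sine[mid])
  expect_lt(abs(amp_ratio - gain), 0.02)
  expect_gt(amp_ratio, 0.99)                 # 25 ms smoothing barely bites
  # linear ramp removed
  ramped <- sine + 0.05 * t
  out2 <- preprocess_resp(ramped, fs)
  slope <- coef(lm(out2 ~ t))[2]
  expect_lt(abs(slope), 1e-3)
  # constant input maps to zero
  expect_equal(preprocess_resp(rep(3, 1000), fs), rep(0, 1000))
  expect_error(preprocess_resp(c(1, 2), 1000), "shorter")
})

test_that("phase detection splits a sinusoid into equal halves", {
  fs <- 50
  t <- seq(0, 720 - 1 / fs, by = 1 / fs)
  ph <- detect_phases(sin(2 * pi * 0.2 * t), fs)
  expect_equal(cycle_count(ph), 144)
  expect_lt(abs(mean(ph$labels == "inhale") - 0.5), 0.01)
})

test_that("phase labels and cycle counts survive affine rescaling", {
  cfg <- sim_config(duration = 120, seed = 14)
  r <- gen_respiration(cfg)
  x <- preprocess_resp(r$trace, cfg$fs_physio)
  a <- detect_phases(x, cfg$fs_physio)
  b <- detect_phases(5 * x + 2, cfg$fs_physio)
  expect_identical(a$labels, b$labels)
  expect_identical(a$onsets, b$onsets)
})

test_that("a flat trace yields an empty flagged phase series", {
  expect_warning(ph <- detect_phases(rep(0, 1000), 100), "no respiratory")
  expect_equal(cycle_count(ph), 0)
})

test_that("channel selection keeps the series with more cycles", {
  many <- make_phase(rep(c(rep("inhale", 5), rep("exhale", 5)), 30))
  few <- make_phase(rep(c(rep("inhale", 25), rep("exhale", 25)), 6))
  expect_identical(attr(select_channel(many, few), "which"), "chest")
  expect_identical(attr(select_channel(few, many), "which"), "abdomen")
  expect_message(tie <- select_channel(many, many), "chest")
  expect_identical(attr(tie, "which"), "chest")
  empty <- make_phase(character(0))
  expect_error(select_channel(empty, empty), "no respiratory")
})

test_that("resampled baseline estimates the inhale fraction", {
  all_in <- make_phase(rep("inhale", 500))
  expect_equal(inhalation_baseline(all_in, 1000, seed = 1), 1)
  balanced <- make_phase(rep(c("inhale", "exhale"), 2500))
  b <- inhalation_baseline(balanced, 10000, seed = 2)
  expect_lt(abs(b - 0.5), 3 * sqrt(0.25 / 10000))
  expect_identical(inhalation_baseline(balanced, 10000, seed = 3),
                   inhalation_baseline(balanced, 10000, seed = 3))
  # unbiased across seeds
  asym <- make_phase(rep(c(rep("inhale", 3), rep("exhale", 7)), 100))
  bs <- vapply(1:200, function(s) inhalation_baseline(asym, 500, seed = s),
               1.0)
  expect_lt(abs(mean(bs) - 0.3), 0.01)
})

test_that("inhalation-rate test needs at least two participants", {
  ph <- make_phase(rep(c("inhale", "exhale"), 100))
  expect_error(inhalation_rate_test(list(ph), list(c(5, 8)), 0.5),
               "two participants")
})

test_that("reports locked to inhalation produce a significant offset-0 rate", {
  set.seed(42)
  n_sub <- 30
  phases <- list(); reports <- list()
  for (p in seq_len(n_sub)) {
    lab <- rep(rep(c("inhale", "exhale"), each = 20), 50)  # fs 10: 2s/2s
    phases[[p]] <- make_phase(lab, fs = 10)
    # reports mostly 0.5 s into inhalation, a few falling in exhalation
    starts <- (which(diff(lab == "inhale") == 1) + 1) / 10
    rp <- sample(starts, 10) + 0.5
    miss <- runif(10) < 0.15
    rp[miss] <- rp[miss] + 2
    reports[[p]] <- rp
  }
  base <- rep(0.5, n_sub)
  res <- inhalation_rate_test(phases, reports, base, offsets = 0:3)
  expect_lt(res$p[res$offset == 0], 0.001)
  expect_gt(res$rate[res$offset == 0], 0.75)   # ~85% locked by design
  # rates are proportions; inhale + exhale rates sum to one
  expect_true(all(res$rate >= 0 & res$rate <= 1))
})

test_that("unlocked reports keep the type-I rate near nominal", {
  set.seed(7)
  rej <- vapply(1:200, function(k) {
    phases <- list(); reports <- list()
    for (p in 1:12) {
      off <- sample(0:39, 1)
      lab <- rep(rep(c("inhale", "exhale"), each = 20), 30)[
        (off + 1):(off + 1000)]
      phases[[p]] <- make_phase(lab, fs = 10)
      reports[[p]] <- runif(8, 10, 90)
    }
    res <- inhalation_rate_test(phases, reports, rep(0.5, 12), offsets = 0)
    res$p < 0.05
  }, TRUE)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 200)
  expect_gte(mean(rej), 0)
  expect_lte(mean(rej), ci[2] + 0.02)
})
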