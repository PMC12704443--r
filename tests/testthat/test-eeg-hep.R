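# EEG preprocessing, R-peak-locked epoching, inclusion rule, and the
# regression-based baseline correction.

test_that("preprocessing notches line noise and re-references to the mean", {
  fs <- 500
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  eeg <- rbind(sin(2 * pi * 50 * t) + sin(2 * pi * 10 * t),
               0.5 * sin(2 * pi * 50 * t) + rnorm(length(t), 0, 0.1),
               sin(2 * pi * 0.1 * t) + sin(2 * pi * 12 * t),
               rnorm(length(t), 0, 0.2))
  out <- preprocess_eeg(eeg, fs)
  expect_equal(out$fs, 250)
  expect_equal(ncol(out$data), length(t) / 2)
  # average reference: channel mean is zero everywhere, and applying it
  # again changes nothing
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  re <- sweep(out$data, 2, colMeans(out$data))
  expect_equal(re, out$data)
  # 50 Hz content suppressed by > 20 dB
  probe <- function(x) {
    sp <- Mod(stats::fft(x))^2
    f <- (seq_along(x) - 1) * 250 / length(x)
    sum(sp[f > 49 & f < 51])
  }
  raw50 <- probe(sin(2 * pi * 50 * seq(0, 10 - 1 / 250, by = 1 / 250)))
  expect_lt(probe(out$data[1, 1:2500]) / raw50, 0.01)
  expect_error(preprocess_eeg(eeg, 200), "below")
  expect_error(preprocess_eeg(eeg, 600), "integer multiple")
})

test_that("slow drift is removed by the 0.5 Hz high-pass", {
  fs <- 250
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  eeg <- rbind(sin(2 * pi * 0.1 * t), sin(2 * pi * 10 * t))
  out <- preprocess_eeg(eeg, fs, line_freq = NA)
  # the channel difference cancels the common average reference, leaving
  # the filtered drift (ch 1) against the filtered 10 Hz rhythm (ch 2)
  sp <- Mod(stats::fft(out$data[1, ] - out$data[2, ]))^2
  f <- (seq_along(t) - 1) * fs / length(t)
  expect_lt(sum(sp[f > 0.05 & f < 0.15]) / sum(sp[f > 9 & f < 11]), 0.01)
})

test_that("epochs span -200 to 600 ms around each usable peak", {
  fs <- 250
  n <- 30 * fs
  eeg <- structure(list(data = matrix(rnorm(2 * n), 2, n), fs = fs,
                        montage = NULL, reference = "average"),
                   class = "eeg_recording")
  ep <- data.frame(state = "MW", t_start = 5, t_end = 25, anchor = 30,
                   condition = "BF", session = 1)
  hep <- epoch_hep(eeg, c(0.1, 10, 20, 29.9), epochs = ep)
  # the peak 0.1 s from the start and the ones outside the epoch drop
  expect_equal(dim(hep$epochs)[1], 2)
  expect_equal(range(hep$times), c(-0.2, 0.6))
  i10 <- which(hep$meta$beat_time == 10)
  sl <- round((10 - 0.2) * fs):round((10 + 0.6) * fs) + 1
  expect_equal(hep$epochs[i10, 1, ], eeg$data[1, sl])
})

test_that("inclusion keeps participants at ten or more reports", {
  counts <- c(a = 10, b = 9, c = 25)
  expect_message(kept <- inclusion_filter(counts), "excluded.*b")
  expect_setequal(kept, c("a", "c"))
  expect_error(inclusion_filter(c(x = 3, y = 2)), "no participant")
})

test_that("baseline regression removes baseline dependence exactly", {
  set.seed(11)
  fs <- 250
  n_tr <- 40
  times <- seq(-0.2, 0.6, by = 1 / fs)
  bl_idx <- times <= -0.075
  cond <- rep(c("A", "B"), each = n_tr / 2)
  b_half <- rnorm(n_tr / 2)
  b <- c(b_half, b_half)      # identical baselines per condition: exact
                              # orthogonality between condition and b
  epochs <- array(0, c(n_tr, 1, length(times)))
  for (i in seq_len(n_tr)) {
    base_seg <- b[i] + rnorm(sum(bl_idx), 0, 1e-8)
    post <- 2 * b[i] + (cond[i] == "A") * 1.5 + rnorm(sum(!bl_idx), 0, 0.1)
    epochs[i, 1, ] <- c(base_seg, post)
  }
  hep <- make_hep_set(epochs, fs = fs)
  out <- baseline_regress(hep, cond)
  expect_equal(dim(out$residualized), dim(epochs))   # trials conserved
  bmean <- out$baseline_mean[, 1]
  for (k in which(!bl_idx)) {
    cv <- abs(cov(out$residualized[, 1, k], bmean))
    expect_lt(cv, 1e-10)
  }
  # condition contrast survives residualization
  resid_post <- rowMeans(out$residualized[, 1, !bl_idx])
  expect_equal(mean(resid_post[cond == "A"]) - mean(resid_post[cond == "B"]),
               1.5, tolerance = 0.1)
})

test_that("a constant baseline drops the covariate with a message", {
  epochs <- array(rnorm(10 * 1 * 201), c(10, 1, 201))
  epochs[, 1, 1:32] <- 5     # constant baseline window
  hep <- make_hep_set(epochs)
  expect_message(out <- baseline_regress(hep, rep(c("A", "B"), 5)),
                 "constant baseline")
  expect_equal(out$residualized[, 1, 100], epochs[, 1, 100])
})

test_that("shuffled condition labels leave no systematic interaction", {
  set.seed(21)
  fs <- 250
  n_tr <- 60
  times <- seq(-0.2, 0.6, by = 1 / fs)
  bl_idx <- times <= -0.075
  ests <- vapply(1:30, function(k) {
    b <- rnorm(n_tr)
    cond <- sample(rep(c("A", "B"), n_tr / 2))
    epochs <- array(0, c(n_tr, 1, length(times)))
    for (i in seq_len(n_tr))
      epochs[i, 1, ] <- c(b[i] + rnorm(sum(bl_idx), 0, 0.01),
                          2 * b[i] + rnorm(sum(!bl_idx), 0, 0.5))
    hep <- make_hep_set(epochs, fs = fs)
    # interaction estimate at one post-peak sample
    bm <- rowMeans(epochs[, 1, bl_idx])
    C <- stats::model.matrix(~ factor(cond),
                             contrasts.arg =
                               list(`factor(cond)` = "contr.sum"))
    fit <- lm(epochs[, 1, 150] ~ C[, 2] * bm)
    coef(fit)[["C[, 2]:bm"]]
  }, 1.0)
  expect_lt(abs(mean(ests)), 0.1)
})
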