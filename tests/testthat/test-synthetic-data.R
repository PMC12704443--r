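# Synthetic-data generator: determinism, ground-truth consistency, and
# recovery of truth by the downstream detectors.

test_that("config validation rejects impossible study parameters", {
  expect_error(sim_config(resp_rate = -1), "resp_rate")
  expect_error(sim_config(alpha_cp_time = 10), "pre-report window")
  expect_error(sim_config(alpha_cp_time = 0.2), "pre-report window")
  cfg <- sim_config(rsa_gain = 80, base_hr = 60)
  resp <- gen_respiration(cfg)
  expect_error(gen_ecg(cfg, resp), "rsa_gain")
})

test_that("a fixed seed reproduces the recording exactly", {
  cfg <- sim_config(duration = 40, n_mw_reports = 1, seed = 7)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$eeg, b$eeg)
  expect_identical(a$ecg, b$ecg)
  expect_identical(a$resp_chest, b$resp_chest)
  expect_identical(a$events, b$events)
})

test_that("noiseless respiration at 12 cpm has exactly rate*duration cycles", {
  cfg <- sim_config(duration = 720, resp_rate = 12, resp_rate_var = 0,
                    resp_phase0 = 0, drift_slope = 0,
                    noise_sd = c(eeg = 2, ecg = 0.04, resp = 0),
                    n_mw_reports = 0, fs_physio = 50)
  r <- gen_respiration(cfg)
  expect_equal(cycle_count(r$phase), 720 * 12 / 60)
  # truth labels partition every sample
  expect_false(anyNA(r$phase$labels))
})

test_that("inhale fraction follows the configured cycle asymmetry", {
  cfg <- sim_config(duration = 300, inhale_frac = 1 / 3, seed = 3,
                    noise_sd = c(eeg = 2, ecg = 0.04, resp = 0.05))
  r <- gen_respiration(cfg)
  expect_lt(abs(mean(r$phase$labels == "inhale") - 1 / 3), 0.03)
})

test_that("constant-rate ECG without modulation gives RR intervals of 1 s", {
  cfg <- sim_config(duration = 60, base_hr = 60, rsa_gain = 0,
                    event_hr_profile = c(0, 0, 0, 0), n_mw_reports = 0,
                    seed = 2)
  r <- gen_respiration(cfg)
  e <- gen_ecg(cfg, r)
  rr <- diff(e$r_peaks)
  expect_true(all(abs(rr - 1) < 1.5 / cfg$fs_physio))
})

test_that("respiratory sinus arrhythmia lengthens RR during exhalation", {
  cfg <- sim_config(duration = 300, rsa_gain = 4, n_mw_reports = 0, seed = 4)
  r <- gen_respiration(cfg)
  e <- gen_ecg(cfg, r)
  idx <- round(e$r_peaks[-length(e$r_peaks)] * cfg$fs_physio) + 1
  lab <- as.character(r$phase$labels)[idx]
  rr <- diff(e$r_peaks)
  expect_gt(mean(rr[lab == "exhale"]), mean(rr[lab == "inhale"]))
})

test_that("the event-locked heart-rate profile shortens RR just before reports", {
  cfg <- sim_config(duration = 200, n_mw_reports = 6,
                    event_hr_profile = c(8, 0, 0, 0), seed = 6)
  rec <- simulate_recording(cfg)
  rrs <- rr_by_second(rec$truth$r_peaks, rec$truth$reports)
  agg <- tapply(rrs$rr, rrs$seconds_before, mean)
  expect_lt(agg[["1"]], agg[["4"]])
})

test_that("tone inter-stimulus intervals stay within 1.2-2 s", {
  cfg <- sim_config(duration = 120, condition = "SF", n_mw_reports = 0,
                    seed = 9)
  ev <- gen_events(cfg)$events
  isi <- diff(ev$onset[ev$type == "tone"])
  expect_true(all(isi >= 1.2 - 1e-9 & isi <= 2 + 1e-9))
})

test_that("zero requested reports yields a tone/press-only table", {
  cfg <- sim_config(duration = 60, n_mw_reports = 0, seed = 5)
  ev <- gen_events(cfg)$events
  expect_setequal(unique(ev$type), c("tone", "press"))
})

test_that("R-peak detector recovers truth beats at over 99% precision/recall", {
  cfg <- sim_config(duration = 150, n_mw_reports = 5, seed = 11)
  rec <- simulate_recording(cfg)
  peaks <- detect_rpeaks(filter_ecg(rec$ecg, rec$fs_physio), rec$fs_physio)
  truth <- rec$truth$r_peaks
  tp <- sum(vapply(peaks$time,
                   function(p) any(abs(truth - p) <= 0.02), TRUE))
  expect_gte(tp / length(truth), 0.99)
  expect_gte(tp / nrow(peaks), 0.99)
})

test_that("phase detector agrees with truth labels on 95% of samples", {
  cfg <- sim_config(duration = 150, n_mw_reports = 5, seed = 11)
  rec <- simulate_recording(cfg)
  ph <- detect_phases(preprocess_resp(rec$resp_chest, rec$fs_physio),
                      rec$fs_physio)
  agree <- mean(as.character(ph$labels) ==
                  as.character(rec$truth$resp_phase$labels), na.rm = TRUE)
  expect_gte(agree, 0.95)
})

test_that("BF breathing is slower than SF breathing by default", {
  rb <- gen_respiration(sim_config(duration = 300, condition = "BF", seed = 8))
  rs <- gen_respiration(sim_config(duration = 300, condition = "SF", seed = 8))
  expect_lt(cycle_count(rb$phase), cycle_count(rs$phase))
})

test_that("injected HEP state contrast appears in the parietal late window", {
  cfg <- sim_config(duration = 200, n_mw_reports = 6, seed = 21,
                    hep_late_amp_by_state = c(MW = 3, aware = 0.5,
                                              focus = 1, other = 1))
  rec <- simulate_recording(cfg)
  pre <- preprocess_eeg(rec$eeg, rec$fs_eeg, montage = rec$montage)
  ep <- label_states(rec$events, recording_end = rec$duration)
  hep <- epoch_hep(pre, rec$truth$r_peaks, epochs = ep)
  hep <- baseline_regress(hep, hep$meta$state)
  avg <- hep_state_average(hep)
  par_idx <- which(rec$montage$parietal)
  tsel <- hep$times >= 0.38 & hep$times <= 0.58
  expect_gt(mean(avg$MW[par_idx, tsel]), mean(avg$aware[par_idx, tsel]))
})

test_that("recording writer emits readable plain-text artifacts", {
  cfg <- sim_config(duration = 40, n_mw_reports = 1, seed = 13)
  rec <- simulate_recording(cfg)
  dir <- withr::local_tempdir()
  paths <- write_recording(rec, dir, signals = TRUE)
  ev <- read_events(paths[["events"]])
  expect_equal(nrow(ev), nrow(rec$events))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$r_peaks, rec$truth$r_peaks, tolerance = 1e-8)
  sig <- utils::read.delim(paths[["physio"]])
  expect_equal(nrow(sig), length(rec$ecg))
})

test_that("band-power course recovers the injected alpha change point", {
  courses <- lapply(1:20, function(p) {
    cfg <- sim_config(duration = 560, n_mw_reports = 20, seed = 500 + p,
                      noise_sd = c(eeg = 0.7, ecg = 0.04, resp = 0.1))
    ev <- gen_events(cfg, seed = 500 + p)
    reports <- ev$events$onset[ev$events$type == "mw_report"]
    ee <- gen_eeg(cfg, r_peaks = numeric(), report_times = reports)
    chs <- which(ee$montage$parietal)
    prereport_power_course(colMeans(ee$eeg[chs, , drop = FALSE]),
                           cfg$fs_eeg, reports, step = 0.5)
  })
  dat <- cp_data_from_courses(courses)
  fit <- suppressWarnings(
    fit_cp_model(dat, chains = 2, iter = 1500, burnin = 500, thin = 2,
                 seed = 31))
  s <- cp_summary(fit)
  expect_lt(abs(s$tau$seconds_before_mean - 4.7), 0.5)
})
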