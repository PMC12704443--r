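# Synthetic multimodal recording generator.  Every generator returns the
# signal together with its ground truth so downstream detectors can be
# scored against known labels.

#' Generate a synthetic respiration belt trace
#'
#' Produces a quasi-sinusoidal flow-like signal with configurable cycle
#' rate, inhale/exhale asymmetry, slow rate variability, linear plus slow
#' sinusoidal drift, and additive measurement noise, together with the
#' true per-sample inhalation/exhalation labels and cycle (inhalation
#' onset) indices.  Drift and noise are injected deliberately so that the
#' preprocessing stage has something to remove.
#'
#' @param cfg a [sim_config()].
#' @param seed optional seed overriding the config-derived one.
#' @return list with `trace` (numeric vector), `phase` (a `phase_series`
#'   with the true labels), and `phi` (the underlying phase in radians).
#' @export
gen_respiration <- function(cfg, seed = NULL) {
  validate_sim_config(cfg)
  if (is.null(seed)) seed <- derive_seeds(cfg$seed, 6)[1]
  with_seed(seed, {
    fs <- cfg$fs_physio
    n <- round(cfg$duration * fs)
    t <- (seq_len(n) - 1) / fs
    f0 <- cfg$resp_rate / 60
    # slowly varying instantaneous rate
    f_t <- f0 * (1 + cfg$resp_rate_var *
                   sin(2 * pi * t / 97 + runif(1, 0, 2 * pi)))
    phi0 <- if (is.null(cfg$resp_phase0)) runif(1, 0, 2 * pi) else cfg$resp_phase0
    # phase-speed warp implements the inhale:exhale duration ratio:
    # inhalation is the rising half (cos(phi) > 0)
    rho <- cfg$inhale_frac
    phi <- numeric(n)
    phi[1] <- phi0
    dphi_base <- 2 * pi * f_t / fs
    for (i in seq_len(n - 1L)) {
      m <- if (cos(phi[i]) > 0) 1 / (2 * rho) else 1 / (2 * (1 - rho))
      phi[i + 1L] <- phi[i] + dphi_base[i] * m
    }
    inhale <- cos(phi) > 0
    # inhalation onsets: crossings into the rising half-cycle
    onsets <- which(diff(inhale) == 1L) + 1L
    trace <- sin(phi) +
      cfg$drift_slope * t +
      0.3 * sin(2 * pi * t / 311 + runif(1, 0, 2 * pi)) * (cfg$drift_slope != 0) +
      rnorm(n, 0, cfg$noise_sd[["resp"]])
    phase <- new_phase_series(
      labels = factor(ifelse(inhale, "inhale", "exhale"),
                      levels = c("inhale", "exhale")),
      onsets = onsets, fs = fs)
    list(trace = trace, phase = phase, phi = phi)
  })
}

# QRS-like template: stylized R spike with Q/S lobes and a T wave.
# Only the R-peak timing matters downstream; the max is exactly at t = 0.
qrs_template <- function(fs, amp = 1) {
  tt <- seq(-0.35, 0.45, by = 1 / fs)
  w <- amp * (exp(-tt^2 / (2 * 0.012^2)) -
                0.25 * exp(-(tt - 0.035)^2 / (2 * 0.015^2)) -
                0.15 * exp(-(tt + 0.030)^2 / (2 * 0.015^2))) +
    0.18 * amp * exp(-(tt - 0.25)^2 / (2 * 0.04^2))
  list(t = tt, w = w, center = which.min(abs(tt)))
}

#' Generate a synthetic ECG trace with known R-peak times
#'
#' Instantaneous heart rate is `base_hr + rsa_gain * cos(phi)` (phi the
#' respiratory phase, so rate is higher during inhalation - respiratory
#' sinus arrhythmia) plus an event-locked offset profile in the seconds
#' before each MW report.  Beats are placed where the integrated rate
#' crosses whole numbers and a fixed QRS-like template is added at each
#' beat.
#'
#' @param cfg a [sim_config()].
#' @param resp output of [gen_respiration()] (RSA is coupled to its phase).
#' @param report_times MW report times in seconds (for the event-locked
#'   heart-rate profile).
#' @param seed optional seed override.
#' @return list with `trace` (mV), `r_peaks` (true R-peak times, s) and
#'   `hr` (instantaneous rate, bpm, per physio sample).
#' @export
gen_ecg <- function(cfg, resp, report_times = numeric(), seed = NULL) {
  validate_sim_config(cfg)
  if (cfg$base_hr - abs(cfg$rsa_gain) <= 0)
    stop("base_hr - |rsa_gain| must be positive", call. = FALSE)
  if (is.null(seed)) seed <- derive_seeds(cfg$seed, 6)[2]
  with_seed(seed, {
    fs <- cfg$fs_physio
    n <- length(resp$trace)
    t <- (seq_len(n) - 1) / fs
    hr <- cfg$base_hr + cfg$rsa_gain * cos(resp$phi)
    prof <- cfg$event_hr_profile
    if (length(prof) && length(report_times)) {
      for (r in report_times) {
        for (k in seq_along(prof)) {
          if (prof[k] == 0) next
          idx <- t > (r - k) & t <= (r - k + 1)
          hr[idx] <- hr[idx] + prof[k]
        }
      }
    }
    # integrated beat count; beats at integer crossings
    beats_cum <- cumsum(hr / 60) / fs
    k_max <- floor(beats_cum[n])
    r_peaks <- approx(x = beats_cum, y = t, xout = seq_len(k_max),
                      ties = "ordered")$y
    r_peaks <- r_peaks[!is.na(r_peaks)]
    tpl <- qrs_template(fs)
    trace <- rnorm(n, 0, cfg$noise_sd[["ecg"]]) +
      0.05 * sin(2 * pi * 0.25 * t)          # baseline wander
    half_pre <- tpl$center - 1L
    for (rp in r_peaks) {
      i0 <- round(rp * fs) + 1L - half_pre
      idx <- seq(i0, i0 + length(tpl$w) - 1L)
      ok <- idx >= 1L & idx <= n
      trace[idx[ok]] <- trace[idx[ok]] + tpl$w[ok]
    }
    # report truth peaks on the sample grid (where the template max lands)
    r_peaks_grid <- (round(r_peaks * fs)) / fs
    list(trace = trace, r_peaks = r_peaks_grid, hr = hr)
  })
}

# 1/f ("pink") background noise via FFT spectral shaping.
pink_noise <- function(n, exponent, sd_target) {
  w <- rnorm(n)
  W <- stats::fft(w)
  f <- c(1e-6, seq_len(n - 1)) # avoid DC blow-up
  f <- pmin(f, n - f)          # two-sided frequency index
  W <- W / (f^(exponent / 2))
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd_target / sd(x)
}

# Two-segment envelope trend before each report.  Slopes are expressed
# in band-POWER units per second (power = envelope amplitude squared),
# so the spectral power course is piecewise linear with a clean slope
# break at the change point: from r - 9.4 power follows slope_pre until
# r - cp and slope_post from there up to the report itself, returning
# to baseline only after the report (the analysis window ends at
# r - 0.5, so no edge artifact leaks in).  The returned series is the
# amplitude envelope, floored at 10% of baseline power.
envelope_with_trend <- function(t, reports, base, slope_pre, slope_post, cp) {
  base_pow <- base^2
  pow <- rep(base_pow, length(t))
  for (r in reports) {
    w0 <- r - 9.4
    w1 <- r
    idx <- which(t >= w0 & t <= w1)
    if (!length(idx)) next
    tt <- t[idx]
    pre <- tt < (r - cp)
    dev <- numeric(length(idx))
    dev[pre] <- slope_pre * (tt[pre] - w0)
    dev_at_cp <- slope_pre * ((r - cp) - w0)
    dev[!pre] <- dev_at_cp + slope_post * (tt[!pre] - (r - cp))
    pow[idx] <- pmax(base_pow + dev, 0.1 * base_pow)
  }
  sqrt(pow)
}

#' Generate synthetic EEG with state-dependent rhythms and a
#' heartbeat-locked deflection
#'
#' Per-channel 1/f background plus alpha (10 Hz) and beta (20 Hz)
#' oscillations whose amplitude envelopes follow a two-segment linear
#' trend with a ground-truth change point before each MW report, plus an
#' R-peak-locked late deflection (Gaussian bump centered 480 ms after the
#' peak, support about 380-580 ms) on parietal channels whose amplitude is
#' set by the attentional state containing the beat.
#'
#' @param cfg a [sim_config()].
#' @param r_peaks true R-peak times in seconds.
#' @param report_times MW report times in seconds.
#' @param epochs optional state epochs (from [label_states()]) used to tag
#'   each heartbeat; beats outside any epoch get state `"other"`.  When
#'   `NULL`, MW/aware windows are derived from `report_times` alone.
#' @param montage montage data frame (defaults to
#'   `sim_montage(cfg$n_channels)`).
#' @param seed optional seed override.
#' @return list with `eeg` (channels x samples, microvolts), `montage`,
#'   and `truth` (injected HEP amplitude and state per beat, envelope
#'   change-point times per report).
#' @export
gen_eeg <- function(cfg, r_peaks, report_times = numeric(), epochs = NULL,
                    montage = NULL, seed = NULL) {
  validate_sim_config(cfg)
  if (is.null(seed)) seed <- derive_seeds(cfg$seed, 6)[3]
  if (is.null(montage)) montage <- sim_montage(cfg$n_channels)
  with_seed(seed, {
    fs <- cfg$fs_eeg
    n <- round(cfg$duration * fs)
    t <- (seq_len(n) - 1) / fs
    env_a <- envelope_with_trend(t, report_times, cfg$alpha_amp,
                                 cfg$alpha_trend_pre, cfg$alpha_trend_post,
                                 cfg$alpha_cp_time)
    env_b <- envelope_with_trend(t, report_times, cfg$beta_amp,
                                 cfg$beta_trend_pre, cfg$beta_trend_post,
                                 cfg$beta_cp_time)
    # state per beat for the HEP amplitude map
    beat_state <- rep("other", length(r_peaks))
    if (is.null(epochs)) {
      for (r in report_times) {
        beat_state[r_peaks >= r - 9 & r_peaks < r - 5] <- "MW"
        beat_state[r_peaks >= r - 5 & r_peaks < r - 1] <- "aware"
      }
    } else {
      for (j in seq_len(nrow(epochs))) {
        inside <- r_peaks >= epochs$t_start[j] & r_peaks < epochs$t_end[j]
        beat_state[inside] <- as.character(epochs$state[j])
      }
    }
    amp_map <- cfg$hep_late_amp_by_state
    beat_amp <- unname(amp_map[beat_state])
    beat_amp[is.na(beat_amp)] <-
      if ("other" %in% names(amp_map)) amp_map[["other"]] else 0
    # heartbeat-locked deflection time course (shared across parietal chans)
    hep_sig <- numeric(n)
    bump_t <- seq(0.30, 0.66, by = 1 / fs)
    bump <- exp(-(bump_t - 0.48)^2 / (2 * 0.04^2))
    for (i in seq_along(r_peaks)) {
      if (beat_amp[i] == 0) next
      i0 <- round(r_peaks[i] * fs) + 1L + round(0.30 * fs)
      idx <- seq(i0, i0 + length(bump) - 1L)
      ok <- idx >= 1L & idx <= n
      hep_sig[idx[ok]] <- hep_sig[idx[ok]] + beat_amp[i] * bump[ok]
    }
    eeg <- matrix(0, nrow = cfg$n_channels, ncol = n,
                  dimnames = list(montage$channel, NULL))
    for (ch in seq_len(cfg$n_channels)) {
      w_a <- if (montage$parietal[ch]) 1 else 0.6   # posterior alpha dominance
      osc <- w_a * env_a * sin(2 * pi * 10 * t + runif(1, 0, 2 * pi)) +
        env_b * sin(2 * pi * 20 * t + runif(1, 0, 2 * pi))
      eeg[ch, ] <- pink_noise(n, cfg$pink_exponent, cfg$noise_sd[["eeg"]]) + osc
      if (montage$parietal[ch]) eeg[ch, ] <- eeg[ch, ] + hep_sig
    }
    truth <- list(beat_state = beat_state, beat_amp = beat_amp,
                  alpha_cp = report_times - cfg$alpha_cp_time,
                  beta_cp = report_times - cfg$beta_cp_time,
                  hep_window = c(0.38, 0.58),
                  parietal = montage$channel[montage$parietal])
    list(eeg = eeg, montage = montage, truth = truth)
  })
}

#' Generate the event table (and heartbeat-counting trials)
#'
#' Places MW reports separated by at least `min_report_gap`, task
#' resumptions 2-4 s after each report, tones with inter-stimulus
#' intervals uniform in \[1.2, 2\] s outside report-to-resume gaps, and key
#' presses with state-dependent reaction-time noise (larger SD within 9 s
#' before a report).  In the BF condition presses are placed at true
#' exhalation ends when `exhale_ends` is supplied.  Also returns a
#' heartbeat-counting task (HCT) trial table with windows of 25-50 s.
#'
#' @param cfg a [sim_config()].
#' @param exhale_ends optional times (s) of true exhalation ends, used for
#'   BF presses.
#' @param seed optional seed override.
#' @return list with `events` (data.frame: onset, type, condition,
#'   session) and `hct` (data.frame: window, actual, reported).
#' @export
gen_events <- function(cfg, exhale_ends = NULL, seed = NULL) {
  validate_sim_config(cfg)
  if (is.null(seed)) seed <- derive_seeds(cfg$seed, 6)[4]
  with_seed(seed, {
    dur <- cfg$duration
    gap <- cfg$min_report_gap
    n_rep <- cfg$n_mw_reports
    reports <- numeric(0)
    if (n_rep > 0) {
      lo <- 15
      hi <- dur - 8
      if (hi - lo < (n_rep - 1) * gap)
        stop("cannot place ", n_rep, " reports separated by ", gap,
             " s in ", dur, " s", call. = FALSE)
      # sequential placement with jitter inside the feasible slack
      slack <- (hi - lo) - (n_rep - 1) * gap
      u <- sort(runif(n_rep, 0, slack))
      reports <- lo + u + gap * (seq_len(n_rep) - 1)
    }
    resumes <- reports + runif(length(reports), 2, 4)
    # tones avoid the report..resume dead time
    tones <- numeric(0)
    tcur <- 1 + runif(1, 0, 0.5)
    while (tcur < dur - 0.5) {
      j <- which(reports <= tcur + 1e-9 & resumes > tcur)
      if (length(j)) tcur <- resumes[max(j)] + runif(1, 1.2, 2)
      if (tcur >= dur - 0.5) break
      tones <- c(tones, tcur)
      tcur <- tcur + runif(1, 1.2, 2)
    }
    in_prereport <- function(x) {
      out <- rep(FALSE, length(x))
      for (r in reports) out <- out | (x >= r - 9 & x < r)
      out
    }
    if (cfg$condition == "BF" && !is.null(exhale_ends)) {
      anchors <- exhale_ends[exhale_ends > 1 & exhale_ends < dur - 1]
      keep <- rep(TRUE, length(anchors))
      for (i in seq_along(reports))
        keep <- keep & !(anchors >= reports[i] & anchors < resumes[i])
      anchors <- anchors[keep]
    } else {
      anchors <- tones
    }
    rt_sd <- ifelse(in_prereport(anchors), cfg$rt_sd_mw, cfg$rt_sd_focus)
    presses <- anchors + pmax(0.12, rnorm(length(anchors), cfg$rt_mean, rt_sd))
    ev <- rbind(
      if (length(tones)) data.frame(onset = tones, type = "tone"),
      if (length(presses)) data.frame(onset = presses, type = "press"),
      if (length(reports)) data.frame(onset = reports, type = "mw_report"),
      if (length(resumes)) data.frame(onset = resumes, type = "resume"))
    ev <- ev[ev$onset >= 0 & ev$onset <= dur, , drop = FALSE]
    ev <- ev[order(ev$onset), , drop = FALSE]
    ev$condition <- cfg$condition
    ev$session <- 1L
    rownames(ev) <- NULL
    windows <- c(25, 30, 35, 40, 45, 50)
    actual <- pmax(1L, round(windows * cfg$base_hr / 60 + rnorm(6, 0, 1)))
    reported <- pmax(0L, round(actual * runif(6, 0.65, 1.05)))
    list(events = ev,
         hct = data.frame(window = windows, actual = actual,
                          reported = reported))
  })
}

#' Simulate a complete synchronized multimodal recording
#'
#' Orchestrates the per-modality generators with deterministic sub-seeds:
#' respiration first (RSA and BF presses depend on it), then events, ECG,
#' and EEG.  A second respiration belt ("abdomen") shares the same
#' underlying cycle but has lower amplitude and doubled noise, so the
#' channel-selection rule has something to choose between.
#'
#' @param cfg a [sim_config()].
#' @return object of class `sim_recording`: list with `eeg` (channels x
#'   samples), `ecg`, `resp_chest`, `resp_abdomen`, `events`, `hct`,
#'   `montage`, sampling rates, and `truth` (R-peak times, phase labels,
#'   change-point times, injected HEP amplitudes, report times).
#' @export
simulate_recording <- function(cfg) {
  validate_sim_config(cfg)
  seeds <- derive_seeds(cfg$seed, 6)
  resp <- gen_respiration(cfg, seed = seeds[1])
  # exhalation ends = inhalation onsets (trough of the cycle)
  exhale_ends <- (resp$phase$onsets - 1) / cfg$fs_physio
  evg <- gen_events(cfg, exhale_ends = exhale_ends, seed = seeds[4])
  reports <- evg$events$onset[evg$events$type == "mw_report"]
  ecg <- gen_ecg(cfg, resp, report_times = reports, seed = seeds[2])
  epochs <- label_states(evg$events, recording_end = cfg$duration)
  eeg <- gen_eeg(cfg, ecg$r_peaks, report_times = reports, epochs = epochs,
                 seed = seeds[3])
  abd <- with_seed(seeds[5], {
    0.55 * (resp$trace - cfg$drift_slope * (seq_along(resp$trace) - 1) /
              cfg$fs_physio) +
      rnorm(length(resp$trace), 0, 2 * cfg$noise_sd[["resp"]])
  })
  rec <- list(eeg = eeg$eeg, ecg = ecg$trace,
              resp_chest = resp$trace, resp_abdomen = abd,
              events = evg$events, hct = evg$hct,
              montage = eeg$montage,
              fs_eeg = cfg$fs_eeg, fs_physio = cfg$fs_physio,
              condition = cfg$condition, duration = cfg$duration,
              truth = list(r_peaks = ecg$r_peaks,
                           resp_phase = resp$phase,
                           reports = reports,
                           epochs = epochs,
                           hep = eeg$truth,
                           hr = ecg$hr),
              config = cfg)
  class(rec) <- "sim_recording"
  rec
}

#' @export
print.sim_recording <- function(x, ...) {
  cat("<sim_recording> ", x$condition, ", ", x$duration, " s, ",
      nrow(x$eeg), " EEG channels @ ", x$fs_eeg, " Hz, ",
      length(x$truth$r_peaks), " heartbeats, ",
      length(x$truth$reports), " MW reports\n", sep = "")
  invisible(x)
}

#' Write a simulated recording to plain-text artifacts
#'
#' Events and signals go to TSV, the ground-truth record to JSON.  Signal
#' TSVs carry one column per channel; times are implicit from the
#' sampling rate recorded in the JSON sidecar.
#'
#' @param rec a `sim_recording`.
#' @param dir output directory (created if missing).
#' @param signals write the (large) signal TSVs as well as events/truth.
#' @return invisibly, the paths written.
#' @export
write_recording <- function(rec, dir, signals = FALSE) {
  stopifnot(inherits(rec, "sim_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(events = file.path(dir, "events.tsv"),
             truth = file.path(dir, "truth.json"),
             meta = file.path(dir, "meta.json"))
  write_events(rec$events, paths["events"])
  truth <- list(r_peaks = rec$truth$r_peaks,
                reports = rec$truth$reports,
                resp_labels = as.character(rec$truth$resp_phase$labels),
                resp_onsets = rec$truth$resp_phase$onsets,
                hep = rec$truth$hep[c("beat_state", "beat_amp", "hep_window",
                                      "parietal")],
                alpha_cp = rec$truth$hep$alpha_cp,
                beta_cp = rec$truth$hep$beta_cp)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(fs_eeg = rec$fs_eeg, fs_physio = rec$fs_physio,
                            condition = rec$condition,
                            duration = rec$duration,
                            channels = rownames(rec$eeg)),
                       paths["meta"], auto_unbox = TRUE, digits = NA)
  if (signals) {
    sig <- file.path(dir, c("eeg.tsv", "physio.tsv"))
    utils::write.table(t(signif(rec$eeg, 6)), sig[1], sep = "\t",
                       row.names = FALSE, col.names = rownames(rec$eeg),
                       quote = FALSE)
    utils::write.table(
      data.frame(ecg = signif(rec$ecg, 6),
                 resp_chest = signif(rec$resp_chest, 6),
                 resp_abdomen = signif(rec$resp_abdomen, 6)),
      sig[2], sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, eeg = sig[1], physio = sig[2])
  }
  invisible(paths)
}
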