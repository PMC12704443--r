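#' Configuration for a synthetic brain-body recording
#'
#' Bundles every parameter of the synthetic-data generator.  Defaults
#' emulate one session of the self-caught paradigm: a participant performs
#' a tone-response (SF, sound-focused) or breath-response (BF,
#' breathing-focused) task, presses a report key whenever they notice mind
#' wandering (MW), and EEG/ECG/respiration are recorded throughout.
#'
#' The injected effects mirror the direction of the phenomena the pipeline
#' is built to detect: alpha and beta envelopes carry a two-segment linear
#' trend with a known change point seconds before each MW report; a
#' heartbeat-locked late deflection (about 380-580 ms after the R peak) on
#' parietal channels whose amplitude depends on attentional state; heart
#' rate modulated by respiratory phase (respiratory sinus arrhythmia, RSA)
#' and by an event-locked profile just before reports; and slower
#' breathing in the BF condition than in the SF condition.
#'
#' @param duration recording length in seconds.
#' @param n_channels number of EEG channels (at least 8).
#' @param fs_eeg,fs_physio sampling rates in Hz for EEG and for
#'   ECG/respiration.
#' @param n_mw_reports number of self-caught MW reports to place.
#' @param condition `"BF"` (breathing-focused) or `"SF"` (sound-focused).
#' @param alpha_cp_time,beta_cp_time ground-truth change-point times, in
#'   seconds before each report, at which the band-envelope trend switches;
#'   must lie inside the pre-report analysis window (0.5 to 9.4 s).
#' @param alpha_trend_pre,alpha_trend_post,beta_trend_pre,beta_trend_post
#'   band-power envelope slopes (square microvolts per second)
#'   before/after the change point; the spectral power course is
#'   piecewise linear with the slope break at the change point.
#' @param alpha_amp,beta_amp baseline oscillation amplitudes in microvolts.
#' @param hep_late_amp_by_state named numeric map (microvolts) of the
#'   heartbeat-locked late deflection amplitude per attentional state;
#'   names among `"MW"`, `"aware"`, `"focus"`, `"other"`.
#' @param base_hr baseline heart rate in beats per minute.
#' @param rsa_gain RSA amplitude in bpm (heart rate is raised during
#'   inhalation and lowered during exhalation by this amount).
#' @param event_hr_profile numeric vector of bpm offsets applied during
#'   the k-th second before each MW report (element k covers the interval
#'   `(report - k, report - k + 1]`).
#' @param resp_rate respiratory rate in cycles per minute; `NULL` picks the
#'   condition default (11 cpm BF, 15 cpm SF - attention to the breath
#'   slows respiration).
#' @param resp_rate_var relative slow variability of the respiratory rate
#'   (0 gives a perfectly regular rhythm).
#' @param inhale_frac fraction of each respiratory cycle spent inhaling.
#' @param resp_phase0 initial respiratory phase in radians, or `NULL` to
#'   draw it at random.
#' @param drift_slope linear drift of the respiration belt signal
#'   (arbitrary units per second).
#' @param noise_sd named numeric vector of additive noise SDs per modality
#'   (`eeg` in microvolts, `ecg` in millivolts, `resp` in arbitrary units).
#' @param pink_exponent spectral exponent of the 1/f EEG background.
#' @param rt_mean,rt_sd_focus,rt_sd_mw reaction-time mean and SDs (s) used
#'   for key presses; the MW/aware value is larger, giving state-dependent
#'   RT variability.
#' @param min_report_gap minimum spacing between MW reports in seconds.
#' @param seed integer master seed; all modalities derive deterministic
#'   sub-seeds from it, so a fixed config yields a byte-identical
#'   recording.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_recording()]
#' @export
sim_config <- function(duration = 300,
                       n_channels = 16,
                       fs_eeg = 250,
                       fs_physio = 250,
                       n_mw_reports = 8,
                       condition = c("BF", "SF"),
                       alpha_cp_time = 4.7,
                       beta_cp_time = 3.5,
                       alpha_trend_pre = 0,
                       alpha_trend_post = -3,
                       beta_trend_pre = 0,
                       beta_trend_post = -0.8,
                       alpha_amp = 4,
                       beta_amp = 2,
                       hep_late_amp_by_state = c(MW = 1.6, aware = 0.6,
                                                 focus = 1.0, other = 1.0),
                       base_hr = 70,
                       rsa_gain = 4,
                       event_hr_profile = c(5, 0, 0, 0),
                       resp_rate = NULL,
                       resp_rate_var = 0.05,
                       inhale_frac = 0.5,
                       resp_phase0 = NULL,
                       drift_slope = 0.02,
                       noise_sd = c(eeg = 2, ecg = 0.04, resp = 0.1),
                       pink_exponent = 1,
                       rt_mean = 0.35,
                       rt_sd_focus = 0.05,
                       rt_sd_mw = 0.12,
                       min_report_gap = 20,
                       seed = 1) {
  condition <- match.arg(condition)
  if (is.null(resp_rate)) resp_rate <- if (condition == "BF") 11 else 15
  cfg <- list(
    duration = duration, n_channels = as.integer(n_channels),
    fs_eeg = fs_eeg, fs_physio = fs_physio,
    n_mw_reports = as.integer(n_mw_reports), condition = condition,
    alpha_cp_time = alpha_cp_time, beta_cp_time = beta_cp_time,
    alpha_trend_pre = alpha_trend_pre, alpha_trend_post = alpha_trend_post,
    beta_trend_pre = beta_trend_pre, beta_trend_post = beta_trend_post,
    alpha_amp = alpha_amp, beta_amp = beta_amp,
    hep_late_amp_by_state = hep_late_amp_by_state,
    base_hr = base_hr, rsa_gain = rsa_gain,
    event_hr_profile = event_hr_profile,
    resp_rate = resp_rate, resp_rate_var = resp_rate_var,
    inhale_frac = inhale_frac, resp_phase0 = resp_phase0,
    drift_slope = drift_slope, noise_sd = noise_sd,
    pink_exponent = pink_exponent,
    rt_mean = rt_mean, rt_sd_focus = rt_sd_focus, rt_sd_mw = rt_sd_mw,
    min_report_gap = min_report_gap, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$duration > 0,
            cfg$fs_eeg > 0, cfg$fs_physio > 0,
            cfg$n_channels >= 8,
            cfg$n_mw_reports >= 0,
            cfg$base_hr > 0,
            cfg$min_report_gap > 0,
            cfg$inhale_frac > 0, cfg$inhale_frac < 1)
  if (cfg$resp_rate <= 0)
    stop("resp_rate must be positive", call. = FALSE)
  if (!cfg$condition %in% c("BF", "SF"))
    stop("condition must be 'BF' or 'SF'", call. = FALSE)
  for (cp in c(cfg$alpha_cp_time, cfg$beta_cp_time))
    if (cp <= 0.5 || cp >= 9.4)
      stop("change-point time must lie inside the pre-report window (0.5, 9.4) s",
           call. = FALSE)
  if (!all(c("eeg", "ecg", "resp") %in% names(cfg$noise_sd)))
    stop("noise_sd needs named entries for eeg, ecg and resp", call. = FALSE)
  invisible(cfg)
}

#' Synthetic EEG montage with 2-D positions
#'
#' Places `n` channels on concentric rings of an idealized head disc and
#' marks a posterior ("parietal") subset used as the target of the
#' injected heartbeat-evoked deflection.
#'
#' @param n number of channels.
#' @return data.frame with columns `channel`, `x`, `y`, `parietal`.
#' @export
sim_montage <- function(n = 16) {
  stopifnot(n >= 8)
  # one central channel, the rest on two rings
  n_inner <- min(7L, n - 1L)
  n_outer <- n - 1L - n_inner
  ang_i <- seq(0, 2 * pi, length.out = n_inner + 1L)[-1L]
  xy <- rbind(c(0, 0),
              cbind(0.45 * sin(ang_i), 0.45 * cos(ang_i)))
  if (n_outer > 0) {
    ang_o <- seq(0, 2 * pi, length.out = n_outer + 1L)[-1L] + pi / n_outer
    xy <- rbind(xy, cbind(0.9 * sin(ang_o), 0.9 * cos(ang_o)))
  }
  df <- data.frame(channel = sprintf("ch%02d", seq_len(n)),
                   x = xy[, 1], y = xy[, 2])
  df$parietal <- df$y < -0.3
  if (!any(df$parietal)) df$parietal[which.min(df$y)] <- TRUE
  df
}
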