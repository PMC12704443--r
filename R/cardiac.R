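# ECG filtering, R-peak detection, RR-interval construction, and the two
# pre-report labeling schemes (by attentional state; by second before
# report).

#' Band-pass filter an ECG trace
#'
#' Zero-phase 3-30 Hz band-pass (forward-backward Butterworth), the
#' standard pre-detection filter that suppresses baseline wander and
#' T waves while keeping the QRS complex.
#'
#' @param x raw ECG (mV).
#' @param fs sampling rate in Hz (must exceed 60 Hz so the 30 Hz edge is
#'   below Nyquist).
#' @param band filter band in Hz.
#' @param order Butterworth order per section.
#' @return filtered trace.
#' @export
filter_ecg <- function(x, fs, band = c(3, 30), order = 2) {
  if (fs <= 60) stop("sampling rate too low for a 3-30 Hz band-pass",
                     call. = FALSE)
  hp <- signal::butter(order, band[1] / (fs / 2), type = "high")
  lp <- signal::butter(order, band[2] / (fs / 2), type = "low")
  y <- signal::filtfilt(hp, x)
  as.numeric(signal::filtfilt(lp, y))
}

#' Detect R peaks with an adaptive rolling threshold
#'
#' Polarity is normalized (a predominantly negative QRS is flipped), a
#' rolling-maximum amplitude threshold selects candidate local maxima,
#' and a refractory period suppresses double detections.  Beats whose RR
#' interval deviates more than `flag_dev` from the local median RR are
#' flagged for review rather than silently dropped (the automated stand-in
#' for visual inspection of misidentified peaks).
#'
#' @param x filtered ECG (see [filter_ecg()]).
#' @param fs sampling rate in Hz.
#' @param refractory minimum distance between peaks in seconds.
#' @param thr_frac threshold as a fraction of the rolling maximum.
#' @param roll_win rolling-maximum window in seconds.
#' @param flag_dev relative RR deviation from the local median that flags
#'   a beat.
#' @return object of class `rpeak_series`: data.frame with `time` (s),
#'   `amplitude`, `flagged`; attribute `fs`.
#' @export
detect_rpeaks <- function(x, fs, refractory = 0.25, thr_frac = 0.45,
                          roll_win = 2, flag_dev = 0.3) {
  n <- length(x)
  if (n == 0 || all(x == 0) || sd(x) == 0) {
    out <- data.frame(time = numeric(), amplitude = numeric(),
                      flagged = logical())
    class(out) <- c("rpeak_series", "data.frame")
    attr(out, "fs") <- fs
    return(out)
  }
  y <- x
  if (abs(min(y)) > abs(max(y))) y <- -y     # polarity normalization
  # block-based local maximum (window ~ roll_win): max over each
  # half-window block and its neighbours, assigned back per sample
  bw <- max(1L, round(roll_win * fs / 2))
  blk <- (seq_len(n) - 1L) %/% bw + 1L
  bmax <- vapply(split(y, blk), max, 1.0)
  nb <- length(bmax)
  loc <- pmax(bmax,
              c(bmax[-1], bmax[nb]),
              c(bmax[1], bmax[-nb]))
  thr <- thr_frac * loc[blk]
  is_peak <- c(FALSE, diff(y) > 0) & c(diff(y) < 0, FALSE) & y > thr
  cand <- which(is_peak)
  if (!length(cand)) {
    out <- data.frame(time = numeric(), amplitude = numeric(),
                      flagged = logical())
    class(out) <- c("rpeak_series", "data.frame")
    attr(out, "fs") <- fs
    return(out)
  }
  refr <- round(refractory * fs)
  kept <- integer(0)
  for (i in cand) {
    if (length(kept) && (i - kept[length(kept)]) < refr) {
      if (y[i] > y[kept[length(kept)]]) kept[length(kept)] <- i
    } else kept <- c(kept, i)
  }
  times <- (kept - 1) / fs
  flagged <- rep(FALSE, length(kept))
  if (length(kept) >= 3) {
    rr <- diff(times)
    med <- zoo::rollapply(zoo::zoo(rr), width = min(11L, length(rr)),
                          FUN = median, fill = NA, partial = TRUE,
                          align = "center")
    dev <- abs(rr - as.numeric(med)) / as.numeric(med)
    flagged[-1] <- dev > flag_dev
  }
  out <- data.frame(time = times, amplitude = y[kept], flagged = flagged)
  class(out) <- c("rpeak_series", "data.frame")
  attr(out, "fs") <- fs
  out
}

#' Beat-to-beat RR intervals from an R-peak series
#'
#' Each interval is tagged with its onset (the earlier beat's time).
#' Intervals outside the physiological plausibility gate (0.25-3 s) are
#' flagged, not removed.
#'
#' @param peaks an `rpeak_series` or numeric vector of peak times (s).
#' @return data.frame with `onset` (s), `rr` (s), `implausible` flag.
#' @export
rr_intervals <- function(peaks) {
  times <- if (is.data.frame(peaks)) peaks$time else peaks
  if (length(times) < 2)
    return(data.frame(onset = numeric(), rr = numeric(),
                      implausible = logical()))
  rr <- diff(times)
  data.frame(onset = times[-length(times)], rr = rr,
             implausible = rr < 0.25 | rr > 3)
}

#' Mean RR interval per attentional state
#'
#' An RR interval belongs to a state when its onset beat falls inside the
#' state epoch (half-open window); the state mean is the ensemble average
#' over all corresponding epochs.
#'
#' @param peaks an `rpeak_series` or numeric vector of peak times.
#' @param epochs state epochs from [label_states()].
#' @return data.frame per state: `state`, `n_beats`, `rr_mean`; states
#'   with no beats get `NA` (flagged by `n_beats = 0`).
#' @export
rr_by_state <- function(peaks, epochs) {
  rr <- rr_intervals(peaks)
  if (!nrow(epochs))
    return(data.frame(state = character(), n_beats = integer(),
                      rr_mean = numeric()))
  state <- rep(NA_character_, nrow(rr))
  for (j in seq_len(nrow(epochs))) {
    inside <- rr$onset >= epochs$t_start[j] & rr$onset < epochs$t_end[j]
    state[inside] <- as.character(epochs$state[j])
  }
  out <- lapply(c("MW", "aware", "focus"), function(s) {
    x <- rr$rr[!is.na(state) & state == s]
    data.frame(state = s, n_beats = length(x),
               rr_mean = if (length(x)) mean(x) else NA_real_)
  })
  do.call(rbind, out)
}

#' Label RR intervals by the second before the MW report
#'
#' A beat occurring d seconds before a report (0 < d <= `horizon`) gets
#' the label `ceiling(d)`: beats under 1 s before the report are labeled
#' 1 s, beats between 1 and 2 s are labeled 2 s, and a beat exactly on a
#' bin edge belongs to that bin (2.0 s before -> "2 s"; half-open
#' `(k-1, k]` convention).  Several beats in one bin all carry that
#' bin's label.
#'
#' @param peaks an `rpeak_series` or numeric vector of peak times.
#' @param report_times MW report times (s).
#' @param horizon how many seconds before the report to label (<= 9).
#' @return data.frame of RR intervals with added `seconds_before`
#'   (integer label, `NA` beyond the horizon) and `report` (anchor time).
#' @export
rr_by_second <- function(peaks, report_times, horizon = 4) {
  stopifnot(horizon <= 9)
  rr <- rr_intervals(peaks)
  rr$seconds_before <- NA_integer_
  rr$report <- NA_real_
  for (r in report_times) {
    d <- r - rr$onset
    sel <- d > 0 & d <= horizon
    rr$seconds_before[sel] <- as.integer(ceiling(d[sel]))
    rr$report[sel] <- r
  }
  rr
}

#' Tag pre-report RR intervals with the dominant respiratory phase window
#'
#' Uses the fixed time-window proxy: beats 0-2 s before the report are
#' tagged as the inhalation-dominant period and beats 2-4 s before as the
#' exhalation-dominant period (interval convention `(0,2]` / `(2,4]`,
#' matching the per-second labels 1-2 and 3-4).  This is a proxy label
#' tied to the report-locked respiratory pattern, not the instantaneous
#' phase.
#'
#' @param peaks an `rpeak_series` or numeric vector of peak times.
#' @param report_times MW report times (s).
#' @return data.frame of RR intervals with `resp_window` in
#'   `c("inhalation", "exhalation", NA)`.
#' @export
label_rr_resp_phase <- function(peaks, report_times) {
  rr <- rr_by_second(peaks, report_times, horizon = 4)
  rr$resp_window <- ifelse(is.na(rr$seconds_before), NA_character_,
                           ifelse(rr$seconds_before <= 2, "inhalation",
                                  "exhalation"))
  rr
}
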