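# Morlet wavelet time-frequency decomposition and the two power
# summaries: state-averaged channel x frequency maps and the continuous
# pre-report power time course.

#' Number of wavelet cycles per frequency
#'
#' Cycles increase linearly from 3 at the lowest analysis frequency:
#' `c(f) = 3 + slope * (f - 2)`.
#'
#' @param freqs frequencies in Hz.
#' @param slope cycles per Hz.
#' @return numeric vector of cycle counts.
#' @export
cycle_rule <- function(freqs, slope = 0.5) {
  3 + slope * (freqs - 2)
}

# Complex Morlet wavelet sampled at fs; sd of the Gaussian envelope in
# time is n_cycles / (2 pi f).
morlet_wavelet <- function(f, n_cycles, fs, n_sd = 3.5) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(n_sd * sigma_t * fs)
  tt <- (-half:half) / fs
  w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma_t^2))
  w / sum(abs(w))                     # unit-gain normalization
}

#' Morlet wavelet spectral power of a single-channel signal
#'
#' Convolves the signal with a complex Morlet wavelet at each frequency
#' (FFT convolution) and returns squared magnitude.  Power scales with
#' the square of signal amplitude.  Samples within one wavelet
#' half-length of either edge are contaminated by the convolution edge;
#' their indices per frequency are returned in the `half_len` attribute
#' so callers can trim them.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param freqs analysis frequencies in Hz (strictly increasing, within
#'   2-40 by default).
#' @param cycles number of cycles per frequency (defaults to
#'   [cycle_rule()]).
#' @return object of class `tfr_power`: frequencies x time matrix of
#'   power with attributes `freqs`, `fs`, `half_len` (samples per
#'   frequency).
#' @export
morlet_tfr <- function(x, fs, freqs = seq(2, 40, by = 1),
                       cycles = cycle_rule(freqs)) {
  stopifnot(length(freqs) == length(cycles), !is.unsorted(freqs))
  n <- length(x)
  pow <- matrix(NA_real_, length(freqs), n)
  half_len <- integer(length(freqs))
  for (i in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[i], cycles[i], fs)
    lw <- length(w)
    if (lw > n)
      stop("signal shorter than the wavelet at ", freqs[i],
           " Hz (", lw, " > ", n, " samples)", call. = FALSE)
    nfft <- stats::nextn(n + lw - 1L, 2)
    conv <- stats::fft(stats::fft(c(x, rep(0, nfft - n))) *
                         stats::fft(c(w, rep(0+0i, nfft - lw))),
                       inverse = TRUE) / nfft
    center <- (lw - 1L) %/% 2L
    pow[i, ] <- Mod(conv[(center + 1L):(center + n)])^2
    half_len[i] <- center
  }
  structure(pow, freqs = freqs, fs = fs, half_len = half_len,
            class = c("tfr_power", "matrix"))
}

#' Time-averaged spectral power per epoch, channel and frequency
#'
#' Computes the Morlet power of each channel within each state epoch and
#' averages over time (each epoch is treated as one stable cognitive
#' state), excluding edge-contaminated samples per frequency.  The
#' trial-level values feed the cluster-based permutation test.
#'
#' @param eeg an `eeg_recording`.
#' @param epochs state epochs from [label_states()].
#' @param freqs analysis frequencies in Hz.
#' @param cycles cycles per frequency.
#' @param pad seconds of signal read on each side of the epoch so that
#'   the full epoch remains edge-clean (must be at least the wavelet
#'   half-length at the lowest frequency).
#' @return list with `power` (trial x channel x frequency array), `meta`
#'   (per-trial state/condition), `freqs`.
#' @export
state_power <- function(eeg, epochs, freqs = seq(2, 40, by = 1),
                        cycles = cycle_rule(freqs), pad = 1) {
  stopifnot(inherits(eeg, "eeg_recording"))
  fs <- eeg$fs
  n <- ncol(eeg$data)
  n_ch <- nrow(eeg$data)
  keep <- which(round((epochs$t_start - pad) * fs) >= 0 &
                  round((epochs$t_end + pad) * fs) < n)
  if (!length(keep)) stop("no epoch fully inside the recording",
                          call. = FALSE)
  pow <- array(NA_real_, c(length(keep), n_ch, length(freqs)))
  for (k in seq_along(keep)) {
    j <- keep[k]
    i0 <- round((epochs$t_start[j] - pad) * fs) + 1L
    i1 <- round((epochs$t_end[j] + pad) * fs) + 1L
    core <- (round(pad * fs) + 1L):(i1 - i0 + 1L - round(pad * fs))
    for (ch in seq_len(n_ch)) {
      tf <- morlet_tfr(eeg$data[ch, i0:i1], fs, freqs, cycles)
      hl <- attr(tf, "half_len")
      for (fi in seq_along(freqs)) {
        valid <- core[core > hl[fi] & core <= (i1 - i0 + 1L) - hl[fi]]
        pow[k, ch, fi] <- mean(tf[fi, valid])
      }
    }
  }
  list(power = pow,
       meta = data.frame(state = as.character(epochs$state[keep]),
                         condition = epochs$condition[keep],
                         anchor = epochs$anchor[keep]),
       freqs = freqs)
}

#' Continuous band-power time course before MW reports
#'
#' For each report, extracts the signal around the pre-report window
#' (plus a wavelet-length margin), computes mean power over the band,
#' and samples it on a uniform grid from `window[1]` to `window[2]`
#' seconds before the report (default 9.4 to 0.5 s - inside this range
#' no sample uses edge-contaminated convolution values).  The per-report
#' courses are averaged into one course per recording.
#'
#' @param x single-channel signal (e.g. a vertex channel).
#' @param fs sampling rate in Hz.
#' @param report_times MW report times (s).
#' @param band band edges in Hz (default alpha, 8-13).
#' @param window seconds before the report: `c(earliest, latest)`.
#' @param step grid step in seconds.
#' @param freq_step spacing of analysis frequencies within the band.
#' @return numeric vector of band power on the grid, with attribute
#'   `times_before` (seconds before the report, decreasing) and
#'   `n_reports` (reports used).  `NULL` (with a message) when no report
#'   window is fully covered.
#' @export
prereport_power_course <- function(x, fs, report_times, band = c(8, 13),
                                   window = c(9.4, 0.5), step = 0.1,
                                   freq_step = 1) {
  freqs <- seq(band[1], band[2], by = freq_step)
  cycles <- cycle_rule(freqs)
  margin <- ceiling(3.5 * cycles[1] / (2 * pi * freqs[1]) * fs) + 1L
  grid <- seq(window[1], window[2], by = -step)
  n <- length(x)
  courses <- list()
  for (r in report_times) {
    i0 <- round((r - window[1]) * fs) + 1L - margin
    i1 <- round((r - window[2]) * fs) + 1L + margin
    if (i0 < 1L || i1 > n) next
    tf <- morlet_tfr(x[i0:i1], fs, freqs, cycles)
    bp <- colMeans(tf)                     # mean over band frequencies
    idx <- round((r - grid) * fs) + 1L - (i0 - 1L)
    courses[[length(courses) + 1L]] <- bp[idx]
  }
  if (!length(courses)) {
    message("no report window fully covered by the recording")
    return(NULL)
  }
  out <- colMeans(do.call(rbind, courses))
  attr(out, "times_before") <- grid
  attr(out, "n_reports") <- length(courses)
  out
}
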