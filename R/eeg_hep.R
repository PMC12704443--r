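# Minimal EEG preprocessing, R-peak-locked epoching, participant
# inclusion, and regression-based HEP baseline correction.

#' Preprocess continuous EEG
#'
#' Downsamples to 250 Hz (anti-aliased, integer decimation), applies a
#' zero-phase 0.5-50 Hz band-pass (separate high- and low-pass
#' Butterworth sections run forward-backward), removes power-line
#' interference by regressing out a sinusoid at the line frequency, and
#' re-references to the channel average.
#'
#' @param eeg channels x samples matrix (microvolts).
#' @param fs input sampling rate in Hz (>= 250 and a multiple of 250).
#' @param montage optional montage data frame carried along.
#' @param target_fs output rate in Hz.
#' @param band band-pass edges in Hz.
#' @param line_freq line frequency in Hz (`NA` to skip the notch).
#' @return object of class `eeg_recording`: list with `data` (channels x
#'   samples), `fs`, `montage`, `reference = "average"`.
#' @export
preprocess_eeg <- function(eeg, fs, montage = NULL, target_fs = 250,
                           band = c(0.5, 50), line_freq = 50) {
  if (fs < target_fs) stop("sampling rate below ", target_fs, " Hz",
                           call. = FALSE)
  if (fs %% target_fs != 0)
    stop("sampling rate must be an integer multiple of ", target_fs, " Hz",
         call. = FALSE)
  dec <- fs %/% target_fs
  if (dec > 1L) {
    aa <- signal::butter(6, 0.8 * (target_fs / 2) / (fs / 2), type = "low")
    eeg <- t(apply(eeg, 1, function(ch) signal::filtfilt(aa, ch)))
    eeg <- eeg[, seq(1, ncol(eeg), by = dec), drop = FALSE]
  }
  hp <- signal::butter(2, band[1] / (target_fs / 2), type = "high")
  lp <- signal::butter(4, band[2] / (target_fs / 2), type = "low")
  eeg <- t(apply(eeg, 1, function(ch)
    signal::filtfilt(lp, signal::filtfilt(hp, ch))))
  if (!is.na(line_freq)) {
    tt <- (seq_len(ncol(eeg)) - 1) / target_fs
    X <- cbind(sin(2 * pi * line_freq * tt), cos(2 * pi * line_freq * tt))
    beta <- solve(crossprod(X), crossprod(X, t(eeg)))
    eeg <- eeg - t(X %*% beta)
  }
  eeg <- sweep(eeg, 2, colMeans(eeg))        # average reference
  structure(list(data = eeg, fs = target_fs, montage = montage,
                 reference = "average"),
            class = "eeg_recording")
}

#' Extract R-peak-locked HEP epochs
#'
#' One epoch per usable R peak, spanning `tmin` to `tmax` seconds around
#' the peak (default -200 to 600 ms).  Peaks whose window crosses the
#' recording edges are dropped.  Each trial is tagged with the
#' attentional state whose epoch contains the beat (and, when supplied,
#' a respiratory-window label); untagged trials are dropped unless
#' `keep_untagged`.
#'
#' @param eeg an `eeg_recording` (see [preprocess_eeg()]).
#' @param peaks an `rpeak_series` or numeric vector of R-peak times (s).
#' @param epochs optional state epochs from [label_states()].
#' @param resp_windows optional data.frame from [label_rr_resp_phase()]
#'   whose `onset`/`resp_window` columns tag beats by respiratory window.
#' @param tmin,tmax epoch bounds in seconds relative to the R peak.
#' @param keep_untagged keep trials with no state tag (state `"other"`).
#' @return object of class `hep_set`: list with `epochs` (trial x channel
#'   x time array), `times` (s), `meta` (per-trial data.frame), `fs`.
#' @export
epoch_hep <- function(eeg, peaks, epochs = NULL, resp_windows = NULL,
                      tmin = -0.2, tmax = 0.6, keep_untagged = FALSE) {
  stopifnot(inherits(eeg, "eeg_recording"))
  times <- if (is.data.frame(peaks)) peaks$time else peaks
  fs <- eeg$fs
  rel <- seq(round(tmin * fs), round(tmax * fs)) / fs
  n_samp <- length(rel)
  n <- ncol(eeg$data)
  centers <- round(times * fs) + 1L
  lo <- centers + round(tmin * fs)
  hi <- lo + n_samp - 1L
  ok <- lo >= 1L & hi <= n
  if (!any(ok)) {
    warning("no usable R peaks for epoching")
    return(structure(list(epochs = array(0, c(0, nrow(eeg$data), n_samp)),
                          times = rel, meta = data.frame(), fs = fs),
                     class = "hep_set"))
  }
  centers <- centers[ok]; lo <- lo[ok]; beat_t <- times[ok]
  state <- rep("other", length(beat_t))
  if (!is.null(epochs) && nrow(epochs)) {
    for (j in seq_len(nrow(epochs))) {
      inside <- beat_t >= epochs$t_start[j] & beat_t < epochs$t_end[j]
      state[inside] <- as.character(epochs$state[j])
    }
  }
  resp_window <- rep(NA_character_, length(beat_t))
  if (!is.null(resp_windows) && nrow(resp_windows)) {
    m <- match(round(beat_t, 6), round(resp_windows$onset, 6))
    resp_window[!is.na(m)] <- resp_windows$resp_window[m[!is.na(m)]]
  }
  keep <- if (keep_untagged) rep(TRUE, length(beat_t))
          else state != "other" | !is.na(resp_window)
  if (!any(keep)) warning("all epochs untagged; returning empty set")
  idx_keep <- which(keep)
  arr <- array(0, c(length(idx_keep), nrow(eeg$data), n_samp),
               dimnames = list(NULL, rownames(eeg$data), NULL))
  for (i in seq_along(idx_keep)) {
    sl <- lo[idx_keep[i]]:(lo[idx_keep[i]] + n_samp - 1L)
    arr[i, , ] <- eeg$data[, sl]
  }
  meta <- data.frame(beat_time = beat_t[idx_keep],
                     state = state[idx_keep],
                     resp_window = resp_window[idx_keep])
  structure(list(epochs = arr, times = rel, meta = meta, fs = fs),
            class = "hep_set")
}

#' Participant inclusion rule for HEP analyses
#'
#' Participants with fewer than `min_reports` MW reports are excluded
#' (too few heartbeats fall in tagged windows for a stable evoked
#' average).
#'
#' @param mw_counts named integer vector of MW report counts.
#' @param min_reports inclusion threshold (default 10, i.e. ten or more
#'   reports are retained).
#' @return character vector of retained participant names.
#' @export
inclusion_filter <- function(mw_counts, min_reports = 10) {
  retained <- names(mw_counts)[mw_counts >= min_reports]
  dropped <- setdiff(names(mw_counts), retained)
  if (length(dropped))
    message("excluded (fewer than ", min_reports, " reports): ",
            paste(dropped, collapse = ", "))
  if (!length(retained))
    stop("no participant meets the inclusion criterion", call. = FALSE)
  retained
}

#' Regression-based HEP baseline correction
#'
#' Instead of subtracting a baseline (whose cardiac artifacts would be
#' pushed into the post-peak window), fits, per channel and time point, a
#' trial-wise linear model
#' `amplitude ~ baseline_mean * condition` (sum-to-zero condition
#' coding, so the intercept is the grand mean) and removes only the
#' variance tied to the baseline-window mean and its interaction with
#' condition.  Condition structure itself is preserved for the later
#' contrasts.  The baseline window is -200 to -75 ms, which avoids the
#' R-peak artifact.
#'
#' @param hep a `hep_set`.
#' @param condition factor (or vector) with one level per trial - the
#'   experimental factor whose interaction with the baseline is removed.
#' @param baseline_window window in seconds used for the baseline mean.
#' @return the `hep_set` with an added `residualized` array of the same
#'   shape (trials in = trials out) and `baseline_mean` matrix
#'   (trial x channel).
#' @export
baseline_regress <- function(hep, condition,
                             baseline_window = c(-0.2, -0.075)) {
  stopifnot(inherits(hep, "hep_set"))
  n_tr <- dim(hep$epochs)[1]
  stopifnot(length(condition) == n_tr)
  cond <- droplevels(factor(condition))
  bl_idx <- which(hep$times >= baseline_window[1] &
                    hep$times <= baseline_window[2])
  n_ch <- dim(hep$epochs)[2]
  res <- hep$epochs
  bmat <- matrix(NA_real_, n_tr, n_ch)
  multi <- nlevels(cond) > 1
  for (ch in seq_len(n_ch)) {
    Y <- hep$epochs[, ch, , drop = TRUE]          # trials x time
    if (n_tr == 1) Y <- matrix(Y, nrow = 1)
    b <- rowMeans(Y[, bl_idx, drop = FALSE])
    bmat[, ch] <- b
    if (sd(b) < 1e-12) {
      message("channel ", ch,
              ": constant baseline; covariate dropped, trials unchanged")
      next
    }
    if (multi) {
      C <- stats::model.matrix(~ cond,
                               contrasts.arg = list(cond = "contr.sum"))
      X <- cbind(C, b = b, C[, -1, drop = FALSE] * b)
      b_cols <- (ncol(C) + 1L):ncol(X)
    } else {
      X <- cbind(1, b = b)
      b_cols <- 2L
    }
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      message("channel ", ch, ": rank-deficient design; interaction dropped")
      X <- X[, seq_len(qrX$rank), drop = FALSE]
      b_cols <- b_cols[b_cols <= qrX$rank]
      qrX <- qr(X)
    }
    beta <- qr.coef(qrX, Y)
    beta[is.na(beta)] <- 0
    if (length(b_cols))
      res[, ch, ] <- Y - X[, b_cols, drop = FALSE] %*%
        beta[b_cols, , drop = FALSE]
  }
  hep$residualized <- res
  hep$baseline_mean <- bmat
  hep$condition <- cond
  hep
}

#' Per-state average HEP waveforms
#'
#' Averages (residualized, when available) epochs within each state tag -
#' the per-participant input to group-level cluster statistics.
#'
#' @param hep a `hep_set` (after [baseline_regress()] if desired).
#' @param by metadata column to average by (`"state"` or
#'   `"resp_window"`).
#' @param use_residualized average the residualized epochs when present.
#' @return named list of channel x time matrices.
#' @export
hep_state_average <- function(hep, by = "state", use_residualized = TRUE) {
  arr <- if (use_residualized && !is.null(hep$residualized))
    hep$residualized else hep$epochs
  tags <- hep$meta[[by]]
  out <- list()
  for (s in unique(stats::na.omit(tags))) {
    sel <- which(!is.na(tags) & tags == s)
    if (!length(sel)) next
    out[[s]] <- apply(arr[sel, , , drop = FALSE], c(2, 3), mean)
  }
  out
}
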