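# Respiration preprocessing, phase detection, channel selection, and the
# resampled-null inhalation-rate analysis before MW reports.

new_phase_series <- function(labels, onsets, fs) {
  stopifnot(is.factor(labels), all(c("inhale", "exhale") %in% levels(labels)),
            !is.unsorted(onsets, strictly = TRUE) || length(onsets) <= 1)
  structure(list(labels = labels, onsets = as.integer(onsets), fs = fs),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat("<phase_series> ", length(x$labels), " samples @ ", x$fs, " Hz, ",
      length(x$onsets), " cycles, inhale fraction ",
      signif(mean(x$labels == "inhale"), 3), "\n", sep = "")
  invisible(x)
}

#' Preprocess a respiration belt trace
#'
#' Applies, in order: mean smoothing with a 25-ms window, global linear
#' detrending (subtracting the fitted regression line), and local drift
#' correction by subtracting a sliding 60-s mean.  All windows use only
#' the samples that exist (no padding), so edge samples are corrected by
#' the valid-window mean.
#'
#' @param x raw trace.
#' @param fs sampling rate in Hz.
#' @param smooth_win smoothing window in seconds.
#' @param baseline_win sliding-baseline window in seconds.
#' @return cleaned numeric vector.
#' @export
preprocess_resp <- function(x, fs, smooth_win = 0.025, baseline_win = 60) {
  w <- max(1L, round(smooth_win * fs))
  if (length(x) <= w)
    stop("trace shorter than the smoothing window", call. = FALSE)
  y <- running_mean(x, w)
  tt <- seq_along(y)
  b <- stats::cov(tt, y) / stats::var(tt)
  a <- mean(y) - b * mean(tt)
  y <- y - (a + b * tt)
  y - running_mean(y, round(baseline_win * fs))
}

# Alternating-extrema reduction: local extrema of x, same-type runs merged
# to the most extreme one, then adjacent peak/trough pairs whose amplitude
# difference is below `prom` are pruned until all survive.
alternating_extrema <- function(x, prom) {
  dx <- diff(x)
  s <- sign(dx)
  s[s == 0] <- 1e-12           # break plateaus deterministically
  cand <- which(diff(s) != 0) + 1L
  if (!length(cand)) return(list(idx = integer(), type = integer()))
  # rising into the point makes it a peak (1), falling makes it a trough (-1)
  type <- ifelse(dx[pmax(cand - 1L, 1L)] > 0, 1L, -1L)
  repeat {
    changed <- FALSE
    # merge consecutive same-type extrema
    keep <- rep(TRUE, length(cand))
    i <- 1L
    while (i < length(cand)) {
      if (type[i] == type[i + 1L]) {
        better <- if (type[i] == 1L) x[cand[i + 1L]] > x[cand[i]]
                  else x[cand[i + 1L]] < x[cand[i]]
        keep[if (better) i else i + 1L] <- FALSE
        cand <- cand[keep[seq_along(cand)]]
        type <- type[keep[seq_along(type)]]
        keep <- rep(TRUE, length(cand))
        changed <- TRUE
      } else i <- i + 1L
    }
    # prune the weakest adjacent pair below the prominence threshold
    if (length(cand) >= 2L) {
      amp <- abs(diff(x[cand]))
      weak <- which(amp < prom)
      if (length(weak)) {
        j <- weak[which.min(amp[weak])]
        cand <- cand[-c(j, j + 1L)]
        type <- type[-c(j, j + 1L)]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(idx = cand, type = type)
}

#' Detect respiratory phases from a cleaned trace
#'
#' Extrema-based segmentation: inhalation runs from each trough to the
#' next peak, exhalation from each peak to the next trough.  Noise
#' extrema are rejected by a prominence criterion (a fraction of the
#' trace interquartile range) and a minimum half-cycle duration, making
#' the labels invariant to affine rescaling of the input.
#'
#' @param x preprocessed trace (see [preprocess_resp()]).
#' @param fs sampling rate in Hz.
#' @param min_halfcycle minimum duration (s) between successive extrema.
#' @param prominence_frac prominence threshold as a fraction of `IQR(x)`.
#' @param presmooth width (s) of an internal mean-smoothing pass that
#'   removes sample-scale noise extrema before segmentation; well below
#'   any physiological half-cycle.
#' @return a `phase_series`: per-sample labels, cycle (inhalation onset)
#'   indices, and `fs`.  Empty (with a warning) when no cycle is found.
#' @export
detect_phases <- function(x, fs, min_halfcycle = 0.5, prominence_frac = 0.25,
                          presmooth = 0.3) {
  x <- running_mean(x, round(presmooth * fs))
  prom <- prominence_frac * IQR(x)
  ext <- alternating_extrema(x, prom)
  # enforce the minimum half-cycle duration: drop the shallower of any
  # too-close pair, restoring alternation as we go
  if (length(ext$idx) >= 2L) {
    min_gap <- round(min_halfcycle * fs)
    idx <- ext$idx; type <- ext$type
    i <- 1L
    while (i < length(idx)) {
      if (idx[i + 1L] - idx[i] < min_gap) {
        # remove the pair; neighbours of equal type will be re-merged below
        idx <- idx[-c(i, i + 1L)]
        type <- type[-c(i, i + 1L)]
        i <- max(i - 1L, 1L)
      } else i <- i + 1L
    }
    # re-merge any same-type neighbours introduced by the pair removal
    if (length(idx) >= 2L) {
      keep <- rep(TRUE, length(idx))
      j <- 1L
      while (j < length(idx)) {
        if (type[j] == type[j + 1L]) {
          better <- if (type[j] == 1L) x[idx[j + 1L]] > x[idx[j]]
                    else x[idx[j + 1L]] < x[idx[j]]
          keep[if (better) j else j + 1L] <- FALSE
          idx <- idx[keep[seq_along(idx)]]; type <- type[keep[seq_along(type)]]
          keep <- rep(TRUE, length(idx))
        } else j <- j + 1L
      }
    }
    ext <- list(idx = idx, type = type)
  }
  n <- length(x)
  if (length(ext$idx) < 2L) {
    warning("no respiratory cycles detected")
    return(new_phase_series(factor(rep(NA, n),
                                   levels = c("inhale", "exhale")),
                            integer(), fs))
  }
  lab <- rep(NA_character_, n)
  idx <- ext$idx; type <- ext$type
  for (k in seq_len(length(idx) - 1L)) {
    seg <- idx[k]:(idx[k + 1L] - 1L)
    lab[seg] <- if (type[k] == -1L) "inhale" else "exhale"
  }
  # extrapolate the open ends from the adjacent segment type
  lab[seq_len(idx[1] - 1L)] <- if (type[1] == 1L) "inhale" else "exhale"
  lab[idx[length(idx)]:n] <- if (type[length(type)] == -1L) "inhale" else "exhale"
  new_phase_series(factor(lab, levels = c("inhale", "exhale")),
                   onsets = idx[type == -1L], fs = fs)
}

#' Number of respiratory cycles
#'
#' Cycles are counted by detected inhalation onsets (troughs).
#'
#' @param phase a `phase_series`.
#' @return integer count.
#' @export
cycle_count <- function(phase) {
  length(phase$onsets)
}

#' Choose between chest and abdominal respiration channels
#'
#' Keeps the series with more detected cycles; ties go to the chest belt
#' (with a message), since thoracic breathing involves less abdominal
#' movement.
#'
#' @param chest,abdomen `phase_series` objects.
#' @return the chosen `phase_series`, with attribute `which` set to
#'   `"chest"` or `"abdomen"`.
#' @export
select_channel <- function(chest, abdomen) {
  nc <- cycle_count(chest)
  na <- cycle_count(abdomen)
  if (nc == 0 && na == 0)
    stop("no respiratory cycles detected on either channel", call. = FALSE)
  if (nc == na) message("equal cycle counts; keeping the chest channel")
  out <- if (na > nc) abdomen else chest
  attr(out, "which") <- if (na > nc) "abdomen" else "chest"
  out
}

#' Baseline inhalation proportion from a resampled null
#'
#' Draws `n_draws` sample indices uniformly with replacement from the
#' whole phase sequence and returns the fraction labeled inhalation -
#' the participant-specific chance level against which pre-report
#' inhalation rates are tested.
#'
#' @param phase a `phase_series`.
#' @param n_draws number of resampled indices.
#' @param seed optional seed for reproducibility.
#' @return baseline proportion in \[0, 1\].
#' @export
inhalation_baseline <- function(phase, n_draws = 10000, seed = NULL) {
  lab <- phase$labels[!is.na(phase$labels)]
  if (!length(lab)) stop("empty phase series", call. = FALSE)
  with_seed(seed, {
    idx <- sample.int(length(lab), n_draws, replace = TRUE)
    mean(lab[idx] == "inhale")
  })
}

#' Inhalation rate at each second before MW reports, against a resampled
#' baseline
#'
#' For each participant and offset k, the inhalation rate is the fraction
#' of reports whose sample at `report - k` seconds is labeled inhalation
#' (the instantaneous label at that time point).  Each participant's rate
#' is compared with their own resampled baseline; across participants a
#' one-sample t test on the differences (rate minus baseline) is run per
#' offset, with Cohen's d the mean difference over its SD.
#'
#' @param phases list of `phase_series`, one per participant.
#' @param reports list of numeric vectors of MW report times (s), aligned
#'   with `phases`.
#' @param baselines numeric vector of per-participant baseline
#'   proportions (see [inhalation_baseline()]).
#' @param offsets integer seconds before the report to test (default 0:5).
#' @return data.frame per offset: `offset`, `rate` (mean across
#'   participants), `baseline`, `t`, `df`, `p`, `d`, `n`.
#' @export
inhalation_rate_test <- function(phases, reports, baselines, offsets = 0:5) {
  stopifnot(length(phases) == length(reports),
            length(phases) == length(baselines))
  keep <- vapply(reports, length, 1L) > 0
  if (any(!keep)) message(sum(!keep), " participant(s) with no reports excluded")
  phases <- phases[keep]; reports <- reports[keep]
  baselines <- baselines[keep]
  if (length(phases) < 2)
    stop("at least two participants with reports are required", call. = FALSE)
  rates <- sapply(seq_along(phases), function(p) {
    ph <- phases[[p]]
    vapply(offsets, function(k) {
      idx <- round((reports[[p]] - k) * ph$fs) + 1L
      idx <- idx[idx >= 1L & idx <= length(ph$labels)]
      if (!length(idx)) return(NA_real_)
      mean(ph$labels[idx] == "inhale", na.rm = TRUE)
    }, 1.0)
  })                                        # offsets x participants
  rates <- matrix(rates, nrow = length(offsets))
  res <- lapply(seq_along(offsets), function(i) {
    diffs <- rates[i, ] - baselines
    diffs <- diffs[!is.na(diffs)]
    if (sd(diffs) < .Machine$double.eps) {
      # degenerate: every participant deviates identically
      return(data.frame(offset = offsets[i],
                        rate = mean(rates[i, ], na.rm = TRUE),
                        baseline = mean(baselines),
                        t = NA_real_, df = length(diffs) - 1, p = NA_real_,
                        d = NA_real_, n = length(diffs)))
    }
    tt <- t.test(diffs)
    data.frame(offset = offsets[i],
               rate = mean(rates[i, ], na.rm = TRUE),
               baseline = mean(baselines),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               d = mean(diffs) / sd(diffs),
               n = length(diffs))
  })
  do.call(rbind, res)
}
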