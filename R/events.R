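# Event-table model, attentional-state labeling around self-caught MW
# reports, and behavioral metrics.

#' Read / write an event table
#'
#' Events are stored as TSV with columns `onset` (seconds from recording
#' start), `type` (`tone`, `press`, `mw_report`, `resume`, `hct_start`,
#' `hct_stop`), `condition` (`BF`/`SF`) and `session`.
#'
#' @param path file path.
#' @return `read_events`: a data.frame sorted by onset within session.
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("onset", "type", "condition", "session")
  if (!all(req %in% names(ev)))
    stop("event table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  ev <- ev[order(ev$session, ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' @rdname read_events
#' @param events event data.frame.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Label attentional-state epochs around MW reports
#'
#' For every retained MW report the mind-wandering state is the window
#' 5-9 s before the report and the aware state (the transition to
#' awareness of MW) is 1-5 s before it; the second immediately before the
#' report is never used.  Windows are half-open `[start, end)`.  Reports
#' occurring within `exclude_within` seconds of the preceding report are
#' excluded (this exclusion is intended for signal epoching; behavioral
#' counts keep all reports).  The focus state is the `focus_len`-second
#' interval starting at the first tone at or after each task resumption.
#' Epochs that extend beyond the recording bounds are dropped.
#'
#' @param events event data.frame (see [read_events()]); must be sorted.
#' @param recording_start,recording_end recording bounds in seconds.
#' @param exclude_within minimum spacing (s) from the previous report for
#'   a report to be retained; use 0 to keep all.
#' @param mw_window,aware_window `c(from, to)` in seconds before the
#'   report (from > to).
#' @param focus_len focus-epoch length in seconds.
#' @return data.frame with columns `state` (`MW`/`aware`/`focus`),
#'   `t_start`, `t_end`, `anchor` (the report or resume onset),
#'   `condition`, `session`.
#' @export
label_states <- function(events, recording_start = 0, recording_end = Inf,
                         exclude_within = 10,
                         mw_window = c(9, 5), aware_window = c(5, 1),
                         focus_len = 4) {
  stopifnot(mw_window[1] > mw_window[2], aware_window[1] > aware_window[2])
  out <- list()
  for (ses in unique(events$session)) {
    ev <- events[events$session == ses, , drop = FALSE]
    if (is.unsorted(ev$onset)) stop("events must be sorted by onset",
                                    call. = FALSE)
    cond <- ev$condition[1]
    reports <- ev$onset[ev$type == "mw_report"]
    retained <- reports
    if (length(reports) > 1 && exclude_within > 0)
      retained <- reports[c(TRUE, diff(reports) >= exclude_within)]
    add <- function(state, t0, t1, anchor) {
      if (t0 < recording_start || t1 > recording_end) return(NULL)
      data.frame(state = state, t_start = t0, t_end = t1, anchor = anchor,
                 condition = cond, session = ses)
    }
    for (r in retained) {
      out[[length(out) + 1L]] <- add("MW", r - mw_window[1], r - mw_window[2], r)
      out[[length(out) + 1L]] <- add("aware", r - aware_window[1],
                                     r - aware_window[2], r)
    }
    resumes <- ev$onset[ev$type == "resume"]
    tones <- ev$onset[ev$type == "tone"]
    for (rs in resumes) {
      tone1 <- tones[tones >= rs]
      if (!length(tone1)) {
        message("no tone after resumption at ", signif(rs, 6),
                " s; focus epoch skipped")
        next
      }
      out[[length(out) + 1L]] <- add("focus", tone1[1], tone1[1] + focus_len, rs)
    }
  }
  if (!length(out))
    return(data.frame(state = character(), t_start = numeric(),
                      t_end = numeric(), anchor = numeric(),
                      condition = character(), session = integer()))
  ep <- do.call(rbind, out)
  ep$state <- factor(ep$state, levels = c("MW", "aware", "focus"))
  ep <- ep[order(ep$session, ep$t_start), , drop = FALSE]
  rownames(ep) <- NULL
  ep
}

#' Per-state reaction time and reaction-time variability
#'
#' Presses are matched to the most recent unmatched tone within
#' `max_latency` seconds; each reaction time is assigned to the state
#' whose epoch contains the tone onset.  RTV is the coefficient of
#' variation sd(RT)/mean(RT) using the sample (n-1) standard deviation.
#' States with fewer than two RTs get `NA` variability (flagged by `n`).
#'
#' @param events event data.frame.
#' @param epochs state epochs from [label_states()].
#' @param max_latency maximum tone-to-press latency (s) for a match.
#' @return data.frame with one row per state: `state`, `n`, `rt_mean`,
#'   `rt_sd`, `rtv`.
#' @export
reaction_metrics <- function(events, epochs, max_latency = 1.2) {
  tones <- events$onset[events$type == "tone"]
  presses <- events$onset[events$type == "press"]
  matched_tone <- rep(NA_real_, length(presses))
  used <- rep(FALSE, length(tones))
  for (i in seq_along(presses)) {
    cand <- which(!used & tones < presses[i] &
                    presses[i] - tones <= max_latency)
    if (length(cand)) {
      j <- cand[length(cand)]
      matched_tone[i] <- tones[j]
      used[j] <- TRUE
    }
  }
  ok <- !is.na(matched_tone)
  rt <- presses[ok] - matched_tone[ok]
  tone_t <- matched_tone[ok]
  state <- rep(NA_character_, length(rt))
  for (j in seq_len(nrow(epochs))) {
    inside <- tone_t >= epochs$t_start[j] & tone_t < epochs$t_end[j]
    state[inside] <- as.character(epochs$state[j])
  }
  res <- lapply(c("MW", "aware", "focus"), function(s) {
    x <- rt[!is.na(state) & state == s]
    data.frame(state = s, n = length(x),
               rt_mean = if (length(x)) mean(x) else NA_real_,
               rt_sd = if (length(x) >= 2) sd(x) else NA_real_,
               rtv = if (length(x) >= 2) sd(x) / mean(x) else NA_real_)
  })
  do.call(rbind, res)
}

#' Interoceptive accuracy score from heartbeat counting
#'
#' `1 - |actual - reported| / actual` per trial; the score is 1 for
#' perfect counting, falls symmetrically for over- and under-counting,
#' and is unbounded below.  `iacc_mean()` averages per-trial scores.
#'
#' @param actual true heartbeat counts (> 0).
#' @param reported reported counts (>= 0).
#' @return numeric vector of per-trial scores.
#' @export
iacc <- function(actual, reported) {
  if (any(actual <= 0)) stop("actual counts must be positive", call. = FALSE)
  if (any(reported < 0)) stop("reported counts must be non-negative",
                              call. = FALSE)
  1 - abs(actual - reported) / actual
}

#' @rdname iacc
#' @param trials data.frame with columns `actual` and `reported`.
#' @export
iacc_mean <- function(trials) {
  mean(iacc(trials$actual, trials$reported))
}
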