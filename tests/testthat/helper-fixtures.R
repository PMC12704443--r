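# Shared fixture builders; everything is generated in code at test time.

# small event table with known structure
make_events <- function(reports = numeric(), resumes = numeric(),
                        tones = numeric(), presses = numeric(),
                        condition = "SF", session = 1L) {
  ev <- rbind(
    if (length(tones)) data.frame(onset = tones, type = "tone"),
    if (length(presses)) data.frame(onset = presses, type = "press"),
    if (length(reports)) data.frame(onset = reports, type = "mw_report"),
    if (length(resumes)) data.frame(onset = resumes, type = "resume"))
  if (is.null(ev)) ev <- data.frame(onset = numeric(), type = character())
  ev$condition <- condition
  ev$session <- session
  ev[order(ev$onset), , drop = FALSE]
}

# minimal hep_set with hand-built epochs (trials x channels x time)
make_hep_set <- function(epochs, fs = 250, tmin = -0.2,
                         meta = NULL) {
  n_time <- dim(epochs)[3]
  times <- tmin + (seq_len(n_time) - 1) / fs
  if (is.null(meta))
    meta <- data.frame(beat_time = seq_len(dim(epochs)[1]),
                       state = "MW", resp_window = NA_character_)
  structure(list(epochs = epochs, times = times, meta = meta, fs = fs),
            class = "hep_set")
}

# phase series with given labels
make_phase <- function(labels, fs = 10, onsets = NULL) {
  lab <- factor(labels, levels = c("inhale", "exhale"))
  if (is.null(onsets)) onsets <- which(diff(lab == "inhale") == 1) + 1L
  selfcaught:::new_phase_series(lab, onsets, fs)
}

# brute-force connected components over a channel x point grid
# (independent oracle for clusterize)
brute_clusters <- function(t_map, threshold, adjacency) {
  n_ch <- nrow(t_map); n_k <- ncol(t_map)
  supra <- which(abs(t_map) > threshold, arr.ind = TRUE)
  if (!nrow(supra)) return(list())
  key <- paste(supra[, 1], supra[, 2])
  parent <- seq_len(nrow(supra))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(supra))) for (j in seq_len(nrow(supra))) {
    if (i >= j) next
    c1 <- supra[i, 1]; k1 <- supra[i, 2]
    c2 <- supra[j, 1]; k2 <- supra[j, 2]
    same_sign <- sign(t_map[c1, k1]) == sign(t_map[c2, k2])
    touch <- (c1 == c2 && abs(k1 - k2) == 1) ||
      (k1 == k2 && adjacency[c1, c2])
    if (same_sign && touch) parent[find(i)] <- find(j)
  }
  roots <- vapply(seq_len(nrow(supra)), find, 1L)
  lapply(split(seq_len(nrow(supra)), roots), function(idx) {
    members <- supra[idx, , drop = FALSE]
    list(members = members, stat = sum(t_map[members]),
         sign = sign(t_map[members[1, , drop = FALSE]]))
  })
}
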