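# Attentional-state labeling, reaction-time metrics, and the heartbeat
# counting score.

test_that("state windows sit at the defined offsets around a report", {
  ev <- make_events(reports = 100, resumes = 103, tones = c(104, 105.5))
  ep <- label_states(ev)
  mw <- ep[ep$state == "MW", ]
  aw <- ep[ep$state == "aware", ]
  fo <- ep[ep$state == "focus", ]
  expect_equal(c(mw$t_start, mw$t_end), c(91, 95))
  expect_equal(c(aw$t_start, aw$t_end), c(95, 99))
  expect_equal(c(fo$t_start, fo$t_end), c(104, 108))
})

test_that("reports within 10 s of the preceding report are excluded", {
  ev <- make_events(reports = c(50, 58))
  ep <- label_states(ev)
  expect_equal(unique(ep$anchor), 50)
  # behavioral counting keeps them: exclusion can be turned off
  ep_all <- label_states(ev, exclude_within = 0)
  expect_setequal(unique(ep_all$anchor), c(50, 58))
})

test_that("windows extending before the recording start are dropped", {
  ev <- make_events(reports = 6)
  ep <- label_states(ev, recording_start = 0)
  expect_false("MW" %in% ep$state)       # [-3, 1) truncated out
  expect_true("aware" %in% ep$state)     # [1, 5) fully inside
  ep2 <- label_states(make_events(reports = 4))
  expect_equal(nrow(ep2), 0)             # aware [-1, 3) also out
})

test_that("a report without resumption still yields its epochs", {
  ev <- make_events(reports = 50)
  ep <- label_states(ev)
  expect_setequal(as.character(ep$state), c("MW", "aware"))
})

test_that("a resumption without a following tone is skipped with a message", {
  ev <- make_events(reports = 50, resumes = 53)
  expect_message(ep <- label_states(ev), "focus epoch skipped")
  expect_false("focus" %in% ep$state)
})

test_that("MW and aware epochs are disjoint 4-s windows for every report", {
  set.seed(1)
  reports <- cumsum(runif(10, 12, 30)) + 15
  ep <- label_states(make_events(reports = reports),
                     recording_end = max(reports) + 10)
  for (r in unique(ep$anchor)) {
    sub <- ep[ep$anchor == r, ]
    expect_equal(sub$t_end - sub$t_start, rep(4, nrow(sub)))
    mw <- sub[sub$state == "MW", ]
    aw <- sub[sub$state == "aware", ]
    expect_lte(mw$t_end, aw$t_start)
  }
  # idempotent on the same sorted table
  expect_identical(ep, label_states(make_events(reports = reports),
                                    recording_end = max(reports) + 10))
})

test_that("reaction metrics compute per-state mean RT and RTV", {
  tones <- c(91.5, 92.9, 95.5, 96.9, 98.2)
  presses <- tones + c(0.4, 0.4, 0.5, 1.0, 1.5)
  ev <- make_events(reports = 100, tones = tones, presses = presses)
  ep <- label_states(ev)
  rm <- reaction_metrics(ev, ep, max_latency = 1.6)
  expect_equal(rm$rtv[rm$state == "MW"], 0)          # identical RTs
  expect_equal(rm$rtv[rm$state == "aware"], 0.5)     # sd .5 / mean 1
  expect_true(is.na(rm$rtv[rm$state == "focus"]))    # no focus epochs
  expect_equal(rm$n[rm$state == "focus"], 0)
})

test_that("a single RT leaves variability undefined", {
  ev <- make_events(reports = 100, tones = 91.5, presses = 91.9)
  rm <- reaction_metrics(ev, label_states(ev))
  expect_equal(rm$n[rm$state == "MW"], 1)
  expect_true(is.na(rm$rtv[rm$state == "MW"]))
})

test_that("presses beyond the latency cap stay unmatched", {
  ev <- make_events(reports = 100, tones = 92, presses = 93.5)
  rm <- reaction_metrics(ev, label_states(ev), max_latency = 1.2)
  expect_equal(sum(rm$n), 0)
})

test_that("heartbeat-counting accuracy follows 1 - |actual-reported|/actual", {
  expect_equal(iacc(50, 50), 1)
  expect_equal(iacc(40, 30), 0.75)
  expect_equal(iacc(40, 50), 0.75)       # symmetric in the difference
  expect_error(iacc(0, 10), "positive")
  # scale invariance
  a <- c(40, 55, 32); r <- c(31, 60, 20)
  expect_equal(iacc(3 * a, 3 * r), iacc(a, r))
  expect_equal(iacc_mean(data.frame(actual = a, reported = r)),
               mean(iacc(a, r)))
})

test_that("event tables round-trip through TSV", {
  ev <- make_events(reports = c(30, 50), resumes = c(33, 54),
                    tones = c(10, 12), presses = c(10.4, 12.5))
  f <- tempfile(fileext = ".tsv")
  write_events(ev, f)
  back <- read_events(f)
  expect_equal(back$onset, sort(ev$onset))
  expect_equal(nrow(back), nrow(ev))
  unlink(f)
})
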