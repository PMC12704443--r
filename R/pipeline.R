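# Configuration and staged orchestration: simulate -> label ->
# respiration / cardiac / hep / tfa -> cluster / changepoint -> report.
# Stage artifacts are files, so any stage can be rerun or tested in
# isolation.

#' Default pipeline configuration
#'
#' Desk-scale defaults: a handful of participants, short recordings,
#' reduced permutation and MCMC budgets.  Every seed is explicit and
#' every stage derives per-participant seeds deterministically.
#'
#' @param out_dir artifact directory.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(out_dir = "selfcaught_run") {
  list(
    out_dir = out_dir,
    seed = 1L,
    n_participants = 4L,
    conditions = c("BF", "SF"),
    sim = list(duration = 150, n_channels = 16, n_mw_reports = 5,
               fs_eeg = 250, fs_physio = 250),
    resp = list(n_draws = 2000, offsets = 0:5),
    hep = list(min_reports = 5),
    tfa = list(band = c(8, 13), channel = 1, step = 0.1),
    cluster = list(n_perm = 200, alpha = 0.025),
    mcmc = list(chains = 2, iter = 1500, burnin = 500, thin = 2))
}

#' Read / write a pipeline configuration
#'
#' Round-trips through YAML unchanged.
#' @param path YAML file.
#' @return `read_pipeline_config`: configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  modifyList(default_pipeline_config(), cfg)
}

#' @rdname read_pipeline_config
#' @param config configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# short provenance fingerprint of a configuration
config_hash <- function(config) {
  txt <- yaml::as.yaml(config)
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 97 + 1)) %%
            .Machine$integer.max)
}

stage_path <- function(config, ...) file.path(config$out_dir, ...)

write_provenance <- function(config, stage, extra = list()) {
  dir.create(stage_path(config, "provenance"), recursive = TRUE,
             showWarnings = FALSE)
  jsonlite::write_json(
    c(list(stage = stage, config_hash = config_hash(config),
           seed = config$seed,
           package_version = as.character(utils::packageVersion("selfcaught")),
           timestamp = format(Sys.time(), tz = "UTC")), extra),
    stage_path(config, "provenance", paste0(stage, ".json")),
    auto_unbox = TRUE)
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    stop("missing artifact ", path, "; run stage '", produced_by,
         "' first", call. = FALSE)
  path
}

participant_ids <- function(config) {
  sprintf("p%02d", seq_len(config$n_participants))
}

rec_file <- function(config, pid, cond)
  stage_path(config, "recordings", paste0(pid, "_", cond, ".rds"))

#' Run one pipeline stage
#'
#' Stages: `simulate`, `label`, `respiration`, `cardiac`, `hep`, `tfa`,
#' `cluster`, `changepoint`, `report`.  Each stage reads the artifacts
#' of its upstream stages from `config$out_dir` (erroring with the name
#' of the stage to run first when one is missing) and writes its own
#' plus a provenance record (config hash, seed, package version).
#'
#' @param stage stage name.
#' @param config configuration list (see [default_pipeline_config()]).
#' @return invisibly, the paths written.
#' @export
run_stage <- function(stage, config = default_pipeline_config()) {
  stages <- c("simulate", "label", "respiration", "cardiac", "hep",
              "tfa", "cluster", "changepoint", "report")
  stage <- match.arg(stage, stages)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fun <- get(paste0("stage_", stage), envir = asNamespace("selfcaught"))
  paths <- fun(config)
  write_provenance(config, stage)
  invisible(paths)
}

#' Run the whole pipeline
#'
#' @param config configuration list.
#' @return invisibly, the path of the final report.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  for (s in c("simulate", "label", "respiration", "cardiac", "hep",
              "tfa", "cluster", "changepoint", "report"))
    run_stage(s, config)
  invisible(stage_path(config, "report.json"))
}

stage_simulate <- function(config) {
  dir.create(stage_path(config, "recordings"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- character(0)
  for (pi in seq_len(config$n_participants)) {
    for (cond in config$conditions) {
      seed <- config$seed + 1000L * pi +
        10000L * match(cond, c("BF", "SF"))
      args <- c(config$sim, list(condition = cond, seed = seed))
      rec <- simulate_recording(do.call(sim_config, args))
      pid <- participant_ids(config)[pi]
      f <- rec_file(config, pid, cond)
      saveRDS(rec, f)
      write_events(rec$events,
                   stage_path(config, "recordings",
                              paste0(pid, "_", cond, "_events.tsv")))
      paths <- c(paths, f)
    }
  }
  paths
}

load_recordings <- function(config) {
  out <- list()
  for (pid in participant_ids(config))
    for (cond in config$conditions) {
      f <- require_artifact(rec_file(config, pid, cond), "simulate")
      out[[paste(pid, cond, sep = "_")]] <- readRDS(f)
    }
  out
}

stage_label <- function(config) {
  recs <- load_recordings(config)
  eps <- do.call(rbind, lapply(names(recs), function(nm) {
    rec <- recs[[nm]]
    ep <- label_states(rec$events, recording_end = rec$duration)
    if (nrow(ep)) ep$participant <- sub("_.*", "", nm)
    ep
  }))
  f <- stage_path(config, "epochs.tsv")
  utils::write.table(eps, f, sep = "\t", row.names = FALSE, quote = FALSE)
  f
}

stage_respiration <- function(config) {
  recs <- load_recordings(config)
  require_artifact(stage_path(config, "epochs.tsv"), "label")
  rates <- list()
  for (cond in config$conditions) {
    phases <- list(); reports <- list(); baselines <- numeric(0)
    cycles <- integer(0)
    for (pid in participant_ids(config)) {
      rec <- recs[[paste(pid, cond, sep = "_")]]
      ph_c <- detect_phases(preprocess_resp(rec$resp_chest, rec$fs_physio),
                            rec$fs_physio)
      ph_a <- detect_phases(preprocess_resp(rec$resp_abdomen,
                                            rec$fs_physio),
                            rec$fs_physio)
      ph <- select_channel(ph_c, ph_a)
      phases[[pid]] <- ph
      reports[[pid]] <- rec$truth$reports
      baselines <- c(baselines,
                     inhalation_baseline(ph, config$resp$n_draws,
                                         seed = config$seed + 77))
      cycles <- c(cycles, cycle_count(ph))
    }
    tst <- inhalation_rate_test(phases, reports, baselines,
                                offsets = config$resp$offsets)
    tst$condition <- cond
    tst$mean_cycles <- mean(cycles)
    rates[[cond]] <- tst
  }
  out <- do.call(rbind, rates)
  f <- stage_path(config, "inhalation_rates.tsv")
  utils::write.table(out, f, sep = "\t", row.names = FALSE, quote = FALSE)
  f
}

stage_cardiac <- function(config) {
  recs <- load_recordings(config)
  ep_f <- require_artifact(stage_path(config, "epochs.tsv"), "label")
  eps <- utils::read.delim(ep_f)
  by_state <- list(); by_sec <- list()
  for (nm in names(recs)) {
    rec <- recs[[nm]]
    pid <- sub("_.*", "", nm)
    peaks <- detect_rpeaks(filter_ecg(rec$ecg, rec$fs_physio),
                           rec$fs_physio)
    ep <- eps[eps$participant == pid & eps$condition == rec$condition, ]
    st <- rr_by_state(peaks, ep)
    st$participant <- pid; st$condition <- rec$condition
    by_state[[nm]] <- st
    sec <- rr_by_second(peaks, rec$truth$reports)
    sec <- sec[!is.na(sec$seconds_before), ]
    if (nrow(sec)) { sec$participant <- pid; sec$condition <- rec$condition }
    by_sec[[nm]] <- sec
  }
  f1 <- stage_path(config, "rr_state.tsv")
  f2 <- stage_path(config, "rr_second.tsv")
  utils::write.table(do.call(rbind, by_state), f1, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(do.call(rbind, by_sec), f2, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  c(f1, f2)
}

stage_hep <- function(config) {
  recs <- load_recordings(config)
  ep_f <- require_artifact(stage_path(config, "epochs.tsv"), "label")
  eps <- utils::read.delim(ep_f)
  counts <- vapply(participant_ids(config), function(pid) {
    sum(vapply(recs[grep(paste0("^", pid, "_"), names(recs))],
               function(r) length(r$truth$reports), 1L))
  }, 1L)
  retained <- inclusion_filter(counts, config$hep$min_reports)
  avgs <- list()
  for (nm in names(recs)) {
    rec <- recs[[nm]]
    pid <- sub("_.*", "", nm)
    if (!pid %in% retained) next
    pre <- preprocess_eeg(rec$eeg, rec$fs_eeg, montage = rec$montage)
    peaks <- detect_rpeaks(filter_ecg(rec$ecg, rec$fs_physio),
                           rec$fs_physio)
    ep <- eps[eps$participant == pid & eps$condition == rec$condition, ]
    hep <- epoch_hep(pre, peaks, epochs = ep)
    if (!nrow(hep$meta)) next
    hep <- baseline_regress(hep, hep$meta$state)
    avgs[[nm]] <- list(avg = hep_state_average(hep),
                       times = hep$times,
                       participant = pid, condition = rec$condition)
  }
  f <- stage_path(config, "hep_averages.rds")
  saveRDS(avgs, f)
  f
}

stage_tfa <- function(config) {
  recs <- load_recordings(config)
  rows <- list()
  for (nm in names(recs)) {
    rec <- recs[[nm]]
    pre <- preprocess_eeg(rec$eeg, rec$fs_eeg, montage = rec$montage)
    crs <- prereport_power_course(pre$data[config$tfa$channel, ], pre$fs,
                                  rec$truth$reports,
                                  band = config$tfa$band,
                                  step = config$tfa$step)
    if (is.null(crs)) next
    rows[[nm]] <- data.frame(participant = sub("_.*", "", nm),
                             condition = rec$condition,
                             time_before = attr(crs, "times_before"),
                             power = as.numeric(crs))
  }
  f <- stage_path(config, "power_course.tsv")
  utils::write.table(do.call(rbind, rows), f, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  f
}

stage_cluster <- function(config) {
  f_hep <- require_artifact(stage_path(config, "hep_averages.rds"), "hep")
  avgs <- readRDS(f_hep)
  recs <- load_recordings(config)
  montage <- recs[[1]]$montage
  adj <- adjacency_from_positions(montage)
  out <- list()
  for (cond in config$conditions) {
    sel <- Filter(function(a) a$condition == cond &&
                    all(c("MW", "aware") %in% names(a$avg)), avgs)
    if (length(sel) < 3) {
      out[[cond]] <- list(skipped = "fewer than 3 participants with both states")
      next
    }
    arr <- function(state) {
      slices <- lapply(sel, function(a) a$avg[[state]])
      a <- array(0, c(length(slices), dim(slices[[1]])))
      for (i in seq_along(slices)) a[i, , ] <- slices[[i]]
      a
    }
    res <- permutation_test(arr("aware"), arr("MW"), adj,
                            n_perm = config$cluster$n_perm,
                            seed = config$seed + 55,
                            alpha = config$cluster$alpha)
    out[[cond]] <- list(
      n_participants = length(sel),
      n_clusters = length(res$clusters),
      clusters = lapply(res$clusters, function(cl)
        list(stat = cl$stat, sign = cl$sign, p = cl$p,
             significant = cl$significant, size = nrow(cl$members))))
  }
  f <- stage_path(config, "hep_clusters.json")
  jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA)
  f
}

stage_changepoint <- function(config) {
  f <- require_artifact(stage_path(config, "power_course.tsv"), "tfa")
  pc <- utils::read.delim(f)
  out <- list()
  for (cond in config$conditions) {
    sub <- pc[pc$condition == cond, ]
    if (!nrow(sub)) next
    wide <- split(sub, sub$participant)
    courses <- lapply(wide, function(d) {
      v <- d$power[order(-d$time_before)]
      attr(v, "times_before") <- sort(d$time_before, decreasing = TRUE)
      v
    })
    dat <- cp_data_from_courses(courses)
    fit <- fit_cp_model(dat, chains = config$mcmc$chains,
                        iter = config$mcmc$iter,
                        burnin = config$mcmc$burnin,
                        thin = config$mcmc$thin,
                        seed = config$seed + 99)
    s <- cp_summary(fit)
    out[[cond]] <- list(
      tau_seconds_before = s$tau$seconds_before_mean,
      tau_ci_seconds = s$tau$seconds_before_ci,
      trend_difference = s$difference$mean,
      difference_ci = s$difference$ci,
      decrease_after_cp = s$difference$decrease_after_cp,
      max_rhat = s$diagnostics$max_rhat,
      min_ess = s$diagnostics$min_ess)
  }
  f <- stage_path(config, "changepoint.json")
  jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA)
  f
}

stage_report <- function(config) {
  pieces <- list()
  for (f in c("inhalation_rates.tsv", "rr_state.tsv")) {
    p <- stage_path(config, f)
    if (file.exists(p)) pieces[[f]] <- utils::read.delim(p)
  }
  for (f in c("hep_clusters.json", "changepoint.json")) {
    p <- stage_path(config, f)
    if (file.exists(p)) pieces[[f]] <- jsonlite::read_json(p)
  }
  f <- stage_path(config, "report.json")
  jsonlite::write_json(list(config_hash = config_hash(config),
                            artifacts = names(pieces),
                            summary = pieces),
                       f, auto_unbox = TRUE, digits = NA)
  f
}
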