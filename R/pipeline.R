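#' Write a session's event streams to a directory
#'
#' Writes the two-table interchange format plus the configuration and
#' schedule needed to reconstruct the session exactly: `trials.csv` (trial,
#' onset_s, label, scene_category, state), `presses.csv` (stream in
#' \{main, detect\}, time_s), `schedule.csv` (segment table), `config.yaml`
#' (flat [session_config()] fields) and `meta.yaml` (critical-period onset).
#' All times are seconds from session start.
#'
#' @param events A `session_events`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(events, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- events$trials
  trials <- data.frame(trial = tr$trial, onset_s = tr$onset,
                       label = tr$label,
                       scene_category = tr$scene_category,
                       state = if ("state" %in% names(tr)) tr$state
                               else NA_character_)
  presses <- data.frame(
    stream = c(rep("main", length(events$main_presses)),
               rep("detect", length(events$detect_presses))),
    time_s = c(events$main_presses, events$detect_presses))
  utils::write.csv(trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(presses, file.path(dir, "presses.csv"), row.names = FALSE)
  write_schedule(events$schedule, file.path(dir, "schedule.csv"))
  write_session_config(events$cfg, file.path(dir, "config.yaml"))
  yaml::write_yaml(list(critical_start = events$schedule$critical_start),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' Validates headers and ordering; an unsorted press stream is an error
#' naming the first offending row. The refresh schedule is rebuilt from the
#' stored critical-period onset, so the round trip is lossless.
#'
#' @param dir Directory containing the session files.
#' @return A `session_events`.
#' @export
read_session <- function(dir) {
  cfg <- read_session_config(file.path(dir, "config.yaml"))
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  need <- c("trial", "onset_s", "label", "scene_category", "state")
  missing <- setdiff(need, names(trials))
  if (length(missing) > 0) {
    stop("trials.csv is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  presses <- utils::read.csv(file.path(dir, "presses.csv"),
                             stringsAsFactors = FALSE)
  if (!all(c("stream", "time_s") %in% names(presses))) {
    stop("presses.csv must have columns `stream`, `time_s`", call. = FALSE)
  }
  bad_stream <- which(!presses$stream %in% c("main", "detect"))
  if (length(bad_stream) > 0) {
    stop("presses.csv row ", bad_stream[1], ": unknown stream `",
         presses$stream[bad_stream[1]], "`", call. = FALSE)
  }
  for (st in c("main", "detect")) {
    tt <- presses$time_s[presses$stream == st]
    if (is.unsorted(tt)) {
      row <- which(presses$stream == st)[which(diff(tt) < 0)[1] + 1L]
      stop("presses.csv row ", row, ": `", st,
           "` stream times are not sorted ascending", call. = FALSE)
    }
    if (any(tt < 0 | tt > cfg$session_duration)) {
      stop("presses.csv: `", st, "` stream has times outside the session",
           call. = FALSE)
    }
  }
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  sched <- build_critical_schedule(meta$critical_start, cfg)
  tr <- data.frame(trial = trials$trial, onset = trials$onset_s,
                   label = trials$label,
                   scene_category = trials$scene_category,
                   state = trials$state)
  structure(list(trials = tr,
                 schedule = sched,
                 main_presses = presses$time_s[presses$stream == "main"],
                 detect_presses = presses$time_s[presses$stream == "detect"],
                 latent_state = tr$state,
                 cfg = cfg,
                 params = NULL),
            class = "session_events")
}

#' One-row summary of a session through the whole analysis chain
#'
#' Runs classification, the VTC analysis and detection coding on one
#' session and returns the participant-level quantities the cohort analyses
#' consume.
#'
#' @param events A `session_events`.
#' @param fwhm VTC smoothing kernel FWHM, trials.
#' @return One-row data.frame.
#' @export
summarize_session <- function(events, fwhm = 9) {
  cfg <- events$cfg
  cs <- assign_presses(events)
  vtc <- run_vtc(cs, fwhm = fwhm)
  rep <- detection_report(events$detect_presses, events$schedule, vtc, cfg)
  crit <- critical_window(events$schedule)
  err <- error_rates_by_state(cs, vtc)
  rate <- function(type, st) err$rate[err$error_type == type &
                                        err$state == st]
  data.frame(
    target_rate = cfg$target_rate,
    accuracy = accuracy_in_window(cs, c(0, cfg$session_duration)),
    accuracy_critical = accuracy_in_window(cs, crit),
    accuracy_noncritical = {
      sel <- cs$trials$onset < crit[1] - 1e-9 |
        cs$trials$onset > crit[2] + 1e-9
      100 * mean(cs$trials$outcome[sel] %in% c("correct_go", "correct_nogo"))
    },
    ambiguous_fraction = cs$ambiguous_fraction,
    omission_rate_in = rate("omission", "in"),
    omission_rate_out = rate("omission", "out"),
    commission_rate_in = rate("commission", "in"),
    commission_rate_out = rate("commission", "out"),
    in_zone_prop_critical = in_zone_proportion(vtc, crit, cfg),
    n_hits = rep$n_hits,
    n_fas = rep$n_fas,
    liberal_correct = rep$liberal_correct,
    conservative_correct = rep$conservative_correct,
    out_zone_press_fraction = rep$out_zone_press_fraction,
    out_zone_press_fraction_excl_critical =
      rep$out_zone_press_fraction_excl_critical)
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates a cohort (split across the target-rate groups), pushes every
#' session through classification, VTC analysis and detection coding, and
#' writes the per-participant table, group-level cohort summary, the
#' error-rate table consumed by downstream mixed-model analyses, and a JSON
#' run manifest recording seeds and outputs.
#'
#' @param out_dir Output directory.
#' @param cfg A [session_config()] or path to a config YAML file. The
#'   `target_rate` field is overridden per group.
#' @param params A [sim_params()].
#' @param n_per_group Participants per target-rate group.
#' @param groups Target refresh rates, Hz.
#' @param seed Master seed; per-participant seeds are derived from it and
#'   recorded in the manifest.
#' @param fwhm VTC smoothing FWHM, trials.
#' @return The manifest (list), invisibly.
#' @export
run_pipeline <- function(out_dir, cfg = session_config(),
                         params = sim_params(), n_per_group = 40,
                         groups = c(30, 20), seed = 1, fwhm = 9) {
  if (is.character(cfg)) cfg <- read_session_config(cfg)
  stopifnot(inherits(cfg, "session_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_total <- n_per_group * length(groups)
  part_seeds <- withr::with_seed(seed,
                                 sample.int(.Machine$integer.max - 1,
                                            n_total))
  grp <- rep(groups, each = n_per_group)
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    cfg_i <- cfg
    cfg_i$target_rate <- grp[i]
    validate_session_config(cfg_i)
    ev <- simulate_session(cfg_i, params, seed = part_seeds[i])
    rows[[i]] <- cbind(participant = i, summarize_session(ev, fwhm = fwhm))
  }
  participants <- do.call(rbind, rows)

  cohort <- do.call(rbind, lapply(groups, function(g) {
    d <- participants[participants$target_rate == g, ]
    data.frame(target_rate = g,
               n = nrow(d),
               liberal_rate = 100 * mean(d$liberal_correct),
               conservative_rate = 100 * mean(d$conservative_correct),
               mean_accuracy = mean(d$accuracy),
               mean_out_zone_press_fraction =
                 mean(d$out_zone_press_fraction, na.rm = TRUE))
  }))

  # long error-rate table: input for off-the-shelf mixed-model analyses
  err_long <- do.call(rbind, lapply(c("omission", "commission"),
    function(type) do.call(rbind, lapply(c("in", "out"), function(st) {
      data.frame(participant = participants$participant,
                 target_rate = participants$target_rate,
                 error_type = type, state = st,
                 rate = participants[[paste0(type, "_rate_", st)]])
    }))))

  # headline within-group test: out-of-zone press proportion vs 0.5
  ozf <- participants$out_zone_press_fraction
  ozf <- ozf[!is.na(ozf)]
  bf <- if (length(ozf) >= 2 && stats::sd(ozf) > 0) {
    jzs_bf_one_sample(ozf, null_value = 0.5)
  } else NULL

  paths <- file.path(out_dir, c("participants.csv", "cohort_summary.csv",
                                "errors_by_state.csv", "manifest.json"))
  utils::write.csv(participants, paths[1], row.names = FALSE)
  utils::write.csv(cohort, paths[2], row.names = FALSE)
  utils::write.csv(err_long, paths[3], row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("gradcpt")),
    created = format(Sys.time(), tz = "UTC"),
    seed = seed,
    participant_seeds = part_seeds,
    groups = grp,
    config = unclass(cfg),
    sim_params = unclass(params)[names(params) != "seed"],
    fwhm = fwhm,
    outputs = basename(paths),
    out_zone_vs_half = if (!is.null(bf)) {
      list(bf10 = bf$bf10, t = bf$t_stat, n = bf$n, band = bf$evidence_band)
    })
  jsonlite::write_json(manifest, paths[4], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
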