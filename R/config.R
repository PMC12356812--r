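#' Session configuration for a gradCPT run
#'
#' Collects every timing and design constant of a gradual-onset continuous
#' performance task (gradCPT) session with a variable-refresh-rate peripheral
#' window into one validated record. Defaults describe an 8-minute session of
#' 600 trials (540 go / 60 no-go, 800 ms each) with 25-ms morph updates, a
#' 180-Hz baseline refresh rate, a stepped ramp to a low target rate (30 or
#' 20 Hz) with a 22-s dwell, and the response-window constants used by the
#' trial classifier.
#'
#' @param session_duration Session length in seconds.
#' @param trial_duration Trial length in seconds.
#' @param morph_update_interval Interval between scene-morph weight updates,
#'   seconds. Must divide `trial_duration` exactly.
#' @param n_trials,n_go,n_nogo Trial counts; `n_go + n_nogo` must equal
#'   `n_trials`, and `n_trials * trial_duration` must equal
#'   `session_duration`.
#' @param baseline_rate Baseline display refresh rate, Hz.
#' @param ramp_rates Intermediate refresh rates stepped through on the way
#'   down to `target_rate`, Hz, strictly decreasing and all above
#'   `target_rate`.
#' @param target_rate Refresh rate held during the critical-period dwell, Hz
#'   (30 or 20 in the two experimental groups).
#' @param dwell_duration Time spent at `target_rate`, seconds.
#' @param rotation_period Time for one full revolution of the peripheral dot,
#'   seconds; invariant across refresh rates.
#' @param onset_exclusion Band at each end of the session, seconds, inside
#'   which the critical period may not fall.
#' @param unambiguous_start_offset Start of a trial's unambiguous response
#'   window, seconds after trial onset.
#' @param unambiguous_end_offset_into_next End of the window, seconds after
#'   the *next* trial's onset.
#' @param assignment_cutoff RT cutoff used when an ambiguous press must be
#'   split between two same-label trials, seconds.
#' @param forbid_consecutive_nogo If `TRUE`, `generate_trial_sequence()`
#'   rejects placements with adjacent no-go trials.
#'
#' @return An object of class `session_config` (a named list).
#' @examples
#' cfg <- session_config()
#' n_morph_steps(cfg)
#' @export
session_config <- function(session_duration = 480,
                           trial_duration = 0.8,
                           morph_update_interval = 0.025,
                           n_trials = 600,
                           n_go = 540,
                           n_nogo = 60,
                           baseline_rate = 180,
                           ramp_rates = c(90, 60, 45, 36),
                           target_rate = 30,
                           dwell_duration = 22,
                           rotation_period = 2,
                           onset_exclusion = 60,
                           unambiguous_start_offset = 0.480,
                           unambiguous_end_offset_into_next = 0.240,
                           assignment_cutoff = 0.480,
                           forbid_consecutive_nogo = FALSE) {
  cfg <- list(
    session_duration = session_duration,
    trial_duration = trial_duration,
    morph_update_interval = morph_update_interval,
    n_trials = as.integer(n_trials),
    n_go = as.integer(n_go),
    n_nogo = as.integer(n_nogo),
    baseline_rate = baseline_rate,
    ramp_rates = ramp_rates,
    target_rate = target_rate,
    dwell_duration = dwell_duration,
    rotation_period = rotation_period,
    onset_exclusion = onset_exclusion,
    unambiguous_start_offset = unambiguous_start_offset,
    unambiguous_end_offset_into_next = unambiguous_end_offset_into_next,
    assignment_cutoff = assignment_cutoff,
    forbid_consecutive_nogo = isTRUE(forbid_consecutive_nogo)
  )
  validate_session_config(cfg)
  structure(cfg, class = "session_config")
}

validate_session_config <- function(cfg) {
  scalar_pos <- c("session_duration", "trial_duration", "morph_update_interval",
                  "baseline_rate", "target_rate", "rotation_period")
  for (f in scalar_pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", f, "` must be a single positive number", call. = FALSE)
    }
  }
  for (f in c("dwell_duration", "onset_exclusion", "unambiguous_start_offset",
              "unambiguous_end_offset_into_next", "assignment_cutoff")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("`", f, "` must be a single non-negative number", call. = FALSE)
    }
  }
  if (cfg$n_trials < 1L) stop("`n_trials` must be at least 1", call. = FALSE)
  if (cfg$n_go < 0L || cfg$n_nogo < 0L) {
    stop("trial counts must be non-negative", call. = FALSE)
  }
  if (cfg$n_go + cfg$n_nogo != cfg$n_trials) {
    stop("`n_go` + `n_nogo` must equal `n_trials`", call. = FALSE)
  }
  if (abs(cfg$n_trials * cfg$trial_duration - cfg$session_duration) > 1e-9) {
    stop("`n_trials` * `trial_duration` must equal `session_duration`",
         call. = FALSE)
  }
  steps <- cfg$trial_duration / cfg$morph_update_interval
  if (abs(steps - round(steps)) > 1e-9) {
    stop("`trial_duration` must be an integer multiple of ",
         "`morph_update_interval`", call. = FALSE)
  }
  if (length(cfg$ramp_rates) > 0) {
    if (any(!is.finite(cfg$ramp_rates)) || any(cfg$ramp_rates <= 0)) {
      stop("`ramp_rates` must be positive and finite", call. = FALSE)
    }
    if (any(diff(cfg$ramp_rates) >= 0)) {
      stop("`ramp_rates` must be strictly decreasing", call. = FALSE)
    }
    if (any(cfg$ramp_rates <= cfg$target_rate)) {
      stop("all `ramp_rates` must exceed `target_rate`", call. = FALSE)
    }
    if (cfg$ramp_rates[1] >= cfg$baseline_rate) {
      stop("`ramp_rates` must lie below `baseline_rate`", call. = FALSE)
    }
  }
  if (cfg$target_rate >= cfg$baseline_rate) {
    stop("`target_rate` must be below `baseline_rate`", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.session_config <- function(x, ...) {
  cat("gradCPT session config:",
      sprintf("%d trials (%d go / %d no-go) x %g s = %g s",
              x$n_trials, x$n_go, x$n_nogo, x$trial_duration,
              x$session_duration), "\n")
  cat("  refresh: baseline", x$baseline_rate, "Hz -> ramp",
      paste(x$ramp_rates, collapse = "/"), "-> target", x$target_rate,
      "Hz, dwell", x$dwell_duration, "s\n")
  invisible(x)
}

#' Read a session configuration from a flat key/value file
#'
#' The file is YAML with scalar (or, for `ramp_rates`, vector) entries whose
#' names mirror the arguments of [session_config()] exactly. Unknown keys are
#' an error, so stale or misspelled fields cannot pass silently.
#'
#' @param path Path to the YAML file.
#' @return A validated `session_config`.
#' @export
read_session_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(session_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(session_config, vals)
}

#' Write a session configuration to a flat key/value file
#'
#' @param cfg A `session_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "session_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
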