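#' Label detection presses as hits or false alarms
#'
#' A press inside the critical period (boundaries closed) is a hit; any
#' press outside it is a false alarm. By default the full critical window —
#' descending ramp, dwell and ascending ramp — counts as critical;
#' `window = "dwell"` restricts to the target-rate dwell for sensitivity
#' analyses.
#'
#' @param detect_presses Sorted press timestamps, seconds.
#' @param sched A `refresh_schedule`.
#' @param window `"full"` (default) or `"dwell"`, see [critical_window()].
#' @return List with `labels` (`"hit"`/`"false_alarm"` per press), `n_hits`,
#'   `n_fas`.
#' @export
label_presses <- function(detect_presses, sched, window = "full") {
  if (is.unsorted(detect_presses)) {
    stop("`detect_presses` must be sorted ascending", call. = FALSE)
  }
  w <- critical_window(sched, window)
  labels <- ifelse(detect_presses >= w[1] - 1e-9 &
                     detect_presses <= w[2] + 1e-9,
                   "hit", "false_alarm")
  list(labels = labels,
       n_hits = sum(labels == "hit"),
       n_fas = sum(labels == "false_alarm"))
}

#' Participant-level detection report
#'
#' Combines hit/false-alarm labelling, the liberal and conservative
#' correctness criteria, and the out-of-the-zone press-proportion analysis
#' into one record.
#'
#' @param detect_presses Sorted press timestamps, seconds.
#' @param sched A `refresh_schedule`.
#' @param epochs A `vtc_result` for the same session.
#' @param cfg A [session_config()].
#' @param window Critical-window definition passed to [label_presses()].
#' @return A `detection_report`: list with `press_labels`, `n_hits`,
#'   `n_fas`, `liberal_correct`, `conservative_correct`,
#'   `out_zone_press_fraction`, `out_zone_press_fraction_excl_critical`
#'   (each `NA` when no press remains).
#' @export
detection_report <- function(detect_presses, sched, epochs, cfg,
                             window = "full") {
  lab <- label_presses(detect_presses, sched, window)
  structure(list(
    press_labels = lab$labels,
    n_hits = lab$n_hits,
    n_fas = lab$n_fas,
    liberal_correct = lab$n_hits >= 1,
    conservative_correct = lab$n_hits >= 1 && lab$n_fas == 0,
    out_zone_press_fraction =
      out_zone_press_proportion(detect_presses, epochs, cfg,
                                exclude_critical = FALSE, sched = sched),
    out_zone_press_fraction_excl_critical =
      out_zone_press_proportion(detect_presses, epochs, cfg,
                                exclude_critical = TRUE, sched = sched)),
    class = "detection_report")
}

#' Did a participant detect the refresh-rate change?
#'
#' Liberal criterion: at least one press during the critical period.
#' Conservative criterion: at least one press during the critical period and
#' none outside it.
#'
#' @param report A `detection_report` (or any list with `n_hits`, `n_fas`).
#' @param criterion `"liberal"` or `"conservative"`.
#' @return Logical.
#' @export
participant_correct <- function(report,
                                criterion = c("liberal", "conservative")) {
  criterion <- match.arg(criterion)
  if (criterion == "liberal") report$n_hits >= 1
  else report$n_hits >= 1 && report$n_fas == 0
}

#' Group detection rate under a criterion
#'
#' @param reports List of `detection_report`s.
#' @param criterion `"liberal"` or `"conservative"`.
#' @return Percent of participants counted correct; `NA` (with a warning)
#'   for an empty list.
#' @export
group_detection_rate <- function(reports,
                                 criterion = c("liberal", "conservative")) {
  criterion <- match.arg(criterion)
  if (length(reports) == 0) {
    warning("no reports; detection rate undefined")
    return(NA_real_)
  }
  100 * mean(vapply(reports, participant_correct, logical(1),
                    criterion = criterion))
}

#' Proportion of detection presses made out-of-the-zone
#'
#' Each press inherits the attentional-state label of the trial whose
#' `[onset, onset + trial_duration)` interval contains it. With
#' `exclude_critical`, presses mapping to trials whose onset lies inside the
#' critical period are dropped before the proportion is formed — this tests
#' whether the in/out asymmetry survives without the hits themselves.
#'
#' @param detect_presses Press timestamps, seconds.
#' @param epochs A `vtc_result`.
#' @param cfg A [session_config()].
#' @param exclude_critical Drop presses in critical-period trials first?
#' @param sched A `refresh_schedule`; required when `exclude_critical`.
#' @return Fraction of remaining presses in out-of-the-zone trials, or `NA`
#'   when none remain (a participant with no analysable press is undefined
#'   for this analysis, not zero).
#' @export
out_zone_press_proportion <- function(detect_presses, epochs, cfg,
                                      exclude_critical = FALSE,
                                      sched = NULL) {
  n <- length(epochs$state)
  trial <- floor(detect_presses / cfg$trial_duration + 1e-9) + 1
  keep <- trial >= 1 & trial <= n
  trial <- trial[keep]
  if (exclude_critical) {
    if (is.null(sched)) {
      stop("`sched` is required when `exclude_critical = TRUE`",
           call. = FALSE)
    }
    onset <- (trial - 1) * cfg$trial_duration
    trial <- trial[onset < sched$critical_start - 1e-9 |
                     onset > sched$critical_end + 1e-9]
  }
  if (length(trial) == 0) return(NA_real_)
  mean(epochs$state[trial] == "out")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf(
    "detection report: %d hits, %d false alarms; liberal %s, conservative %s\n",
    x$n_hits, x$n_fas, x$liberal_correct, x$conservative_correct))
  cat(sprintf("out-of-zone press fraction: %.3f (%.3f excluding critical)\n",
              x$out_zone_press_fraction,
              x$out_zone_press_fraction_excl_critical))
  invisible(x)
}
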