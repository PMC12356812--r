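#' Unambiguous response window of a trial
#'
#' A press is attributable to one trial without rules while that trial's
#' scene is at least a 60/40 morph over its predecessor (from
#' `unambiguous_start_offset`, 480 ms, after its onset) and not yet a 70/30
#' morph into its successor (until `unambiguous_end_offset_into_next`,
#' 240 ms, after the next onset) — a 560-ms band with the defaults.
#'
#' @param trial 1-based trial index.
#' @param cfg A [session_config()].
#' @return `c(start, end)` in seconds; the window is `[start, end)`.
#' @export
unambiguous_window <- function(trial, cfg) {
  onset <- (trial - 1) * cfg$trial_duration
  c(start = onset + cfg$unambiguous_start_offset,
    end = onset + cfg$trial_duration + cfg$unambiguous_end_offset_into_next)
}

#' Assign main-task presses to trials and score outcomes
#'
#' Implements the gradCPT response-classification procedure. Stage 1 assigns
#' every press falling inside a trial's unambiguous window to that trial.
#' Stage 2 resolves each remaining (ambiguous) press, in time order, between
#' its previous and current trial (current = the trial whose onset band
#' contains the press): (a) if exactly one candidate has no assigned press,
#' it takes the press; (b) otherwise, if the candidates differ in label, the
#' go trial takes it; (c) otherwise presses at most `assignment_cutoff`
#' (480 ms) after the current onset go to the previous trial, later ones to
#' the current trial. A trial keeps at most one press (the earliest);
#' surplus presses are discarded and counted. Outcomes follow from label and
#' press presence: `correct_go` (RT = press - onset), `omission`,
#' `correct_nogo`, `commission`.
#'
#' @param events A `session_events`, or a list with elements `trials`
#'   (data.frame with `onset`, `label`) and `main_presses` (sorted seconds).
#' @param cfg A [session_config()]; defaults to `events$cfg`.
#' @return A `classified_session`: list with `trials` (data.frame `trial`,
#'   `onset`, `label`, `press_time`, `rt`, `outcome`, `provenance`),
#'   `ambiguous_fraction` (trials holding a stage-2 press / all trials),
#'   `discarded` (press times), `n_presses`, `cfg`.
#' @export
assign_presses <- function(events, cfg = events$cfg) {
  trials <- events$trials
  presses <- events$main_presses
  if (is.unsorted(presses)) {
    stop("`main_presses` must be sorted ascending", call. = FALSE)
  }
  n <- nrow(trials)
  td <- cfg$trial_duration
  w_lo <- cfg$unambiguous_start_offset
  w_hi <- td + cfg$unambiguous_end_offset_into_next
  cutoff <- cfg$assignment_cutoff
  eps <- 1e-9

  press_time <- rep(NA_real_, n)
  provenance <- rep(NA_character_, n)
  discarded <- numeric(0)

  # window owner of press p, or NA when p is ambiguous. Window k is
  # [onset_k + w_lo, onset_k + w_hi), windows are disjoint when w_hi - w_lo
  # <= td (validated below).
  if (w_hi - w_lo > td + eps) {
    stop("unambiguous windows overlap: window length exceeds trial duration",
         call. = FALSE)
  }
  window_owner <- function(p) {
    k <- as.integer(floor((p - w_lo) / td + eps)) + 1L
    if (k >= 1L && k <= n && (p - (k - 1) * td) < w_hi - eps &&
        (p - (k - 1) * td) >= w_lo - eps) k else NA_integer_
  }

  owner <- vapply(presses, window_owner, integer(1))

  take <- function(k, p, prov) {
    if (is.na(press_time[k])) {
      press_time[k] <<- p
      provenance[k] <<- prov
    } else {
      discarded <<- c(discarded, p)
    }
  }

  # Stage 1: unambiguous presses, in time order
  for (j in which(!is.na(owner))) take(owner[j], presses[j], "unambiguous")

  # Stage 2: ambiguous presses, in time order
  for (j in which(is.na(owner))) {
    p <- presses[j]
    curr <- min(max(floor(p / td + eps) + 1, 1L), n)
    cand <- if (curr > 1) c(curr - 1L, curr) else curr
    free <- is.na(press_time[cand])
    if (sum(free) == 1) {
      take(cand[free], p, "reassigned_no_response")
    } else if (length(cand) == 2 &&
               trials$label[cand[1]] != trials$label[cand[2]]) {
      take(cand[trials$label[cand] == "go"][1], p, "reassigned_go")
    } else if (length(cand) == 2) {
      if (p - trials$onset[curr] <= cutoff + eps) {
        take(cand[1], p, "reassigned_cutoff_prev")
      } else {
        take(cand[2], p, "reassigned_cutoff_curr")
      }
    } else {
      # single occupied candidate (session edge): nothing can take the press
      discarded <- c(discarded, p)
    }
  }

  has_press <- !is.na(press_time)
  outcome <- ifelse(trials$label == "go",
                    ifelse(has_press, "correct_go", "omission"),
                    ifelse(has_press, "commission", "correct_nogo"))
  out <- data.frame(trial = seq_len(n),
                    onset = trials$onset,
                    label = trials$label,
                    press_time = press_time,
                    rt = press_time - trials$onset,
                    outcome = outcome,
                    provenance = provenance)
  structure(list(trials = out,
                 ambiguous_fraction =
                   sum(startsWith(provenance[has_press], "reassigned")) / n,
                 discarded = discarded,
                 n_presses = length(presses),
                 cfg = cfg),
            class = "classified_session")
}

#' @export
print.classified_session <- function(x, ...) {
  tab <- table(factor(x$trials$outcome,
                      c("correct_go", "omission", "correct_nogo",
                        "commission")))
  cat("classified gradCPT session:", nrow(x$trials), "trials\n")
  print(tab)
  cat(sprintf("ambiguous trials: %.2f%%; discarded presses: %d\n",
              100 * x$ambiguous_fraction, length(x$discarded)))
  invisible(x)
}

#' Accuracy over trials whose onset falls in a time window
#'
#' @param cs A `classified_session`.
#' @param window `c(start, end)` in seconds, inclusive at both ends.
#' @return Percent of trials in the window scored `correct_go` or
#'   `correct_nogo`; `NA` (with a warning) if no trial onset falls inside.
#' @export
accuracy_in_window <- function(cs, window) {
  sel <- cs$trials$onset >= window[1] - 1e-9 &
    cs$trials$onset <= window[2] + 1e-9
  if (!any(sel)) {
    warning("no trial onset inside the window; accuracy undefined")
    return(NA_real_)
  }
  100 * mean(cs$trials$outcome[sel] %in% c("correct_go", "correct_nogo"))
}

#' Commission and omission error rates by attentional state
#'
#' @param cs A `classified_session`.
#' @param epochs A `vtc_result` (see [run_vtc()]) supplying the per-trial
#'   in/out-of-the-zone labels; must cover all trials.
#' @return data.frame with columns `error_type` (`commission`/`omission`),
#'   `state` (`in`/`out`), `rate` (proportion of eligible trials; `NA` when
#'   a state holds no eligible trials), `n` (eligible trial count).
#' @export
error_rates_by_state <- function(cs, epochs) {
  if (length(epochs$state) != nrow(cs$trials)) {
    stop("`epochs` must label every trial", call. = FALSE)
  }
  grid <- expand.grid(error_type = c("commission", "omission"),
                      state = c("in", "out"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rate <- NA_real_
  grid$n <- 0L
  for (i in seq_len(nrow(grid))) {
    eligible_label <- if (grid$error_type[i] == "commission") "nogo" else "go"
    sel <- cs$trials$label == eligible_label & epochs$state == grid$state[i]
    grid$n[i] <- sum(sel)
    if (grid$n[i] > 0) {
      grid$rate[i] <- mean(cs$trials$outcome[sel] == grid$error_type[i])
    }
  }
  grid
}
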