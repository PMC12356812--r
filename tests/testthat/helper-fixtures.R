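# Shared fixtures: configs and small random sessions built in code.

default_cfg <- session_config()

# A config scaled down to n trials, keeping all per-trial constants.
small_cfg <- function(n_trials, n_nogo = max(1L, round(n_trials / 10)),
                      ...) {
  session_config(session_duration = n_trials * 0.8,
                 n_trials = n_trials,
                 n_go = n_trials - n_nogo,
                 n_nogo = n_nogo,
                 onset_exclusion = 0,
                 dwell_duration = 2,
                 ...)
}

# Hand-built session: explicit labels and press times, no simulator.
manual_session <- function(labels, presses, cfg = small_cfg(length(labels))) {
  n <- length(labels)
  list(trials = data.frame(trial = seq_len(n),
                           onset = (seq_len(n) - 1) * cfg$trial_duration,
                           label = labels,
                           scene_category = ifelse(labels == "go", "city",
                                                   "mountain")),
       main_presses = sort(presses),
       cfg = cfg)
}

# Random small classification instance for oracle-equivalence testing:
# press times land in every regime (unambiguous bands, ambiguous bands,
# session edges, duplicate targets).
random_instance <- function(n_trials = NULL) {
  n <- if (is.null(n_trials)) sample(3:20, 1) else n_trials
  labels <- sample(c("go", "nogo"), n, replace = TRUE, prob = c(0.7, 0.3))
  n_press <- rpois(1, n * 0.8)
  presses <- sort(runif(n_press, 0, n * 0.8))
  manual_session(labels, presses)
}

# Minimal classified_session from explicit outcomes/RTs (for VTC tests).
manual_classified <- function(outcome, rt,
                              cfg = small_cfg(length(outcome))) {
  n <- length(outcome)
  label <- ifelse(outcome %in% c("correct_go", "omission"), "go", "nogo")
  structure(list(trials = data.frame(
    trial = seq_len(n),
    onset = (seq_len(n) - 1) * cfg$trial_duration,
    label = label,
    press_time = (seq_len(n) - 1) * cfg$trial_duration + rt,
    rt = rt,
    outcome = outcome,
    provenance = ifelse(is.na(rt), NA, "unambiguous")),
    ambiguous_fraction = 0, discarded = numeric(0),
    n_presses = sum(!is.na(rt)), cfg = cfg),
    class = "classified_session")
}
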