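#' Simulation parameters for synthetic gradCPT sessions
#'
#' The generator couples a slowly switching two-state latent attentional
#' state ("in" vs "out" of the zone) to every observable: RT variability,
#' omission and commission lapses, and the hazard of detection presses.
#' Correct-response RTs are lognormal (median `rt_median`, log-scale sd per
#' state) truncated to `(0, 1.04]` s so every press stays inside its trial's
#' assignable range. Detection presses are an inhomogeneous Poisson process
#' whose per-second hazard depends on the latent state and on whether the
#' critical period is in force (`detect_*` inside, `fa_*` outside); at a
#' 20-Hz target rate the in-critical hazards are multiplied by
#' `target_rate_gain`, reflecting the larger per-frame jump of the dot.
#'
#' Defaults place out-of-the-zone above in-the-zone on every lapse and
#' detection channel, make omissions the dominant error, and land overall
#' accuracy near 90 percent.
#'
#' @param rt_median Median correct RT, seconds from trial onset.
#' @param rt_sigma_in,rt_sigma_out Log-scale RT sd per state
#'   (`rt_sigma_out > rt_sigma_in`).
#' @param omission_p_in,omission_p_out P(no press) on a go trial per state.
#' @param commission_p_in,commission_p_out P(press) on a no-go trial per
#'   state.
#' @param state_dwell_mean Mean run length (trials) of the latent state
#'   chain; switching probability is `1 / state_dwell_mean`.
#' @param detect_hazard_in,detect_hazard_out Detection-press hazard (per
#'   second) during the critical period, per state.
#' @param fa_hazard_in,fa_hazard_out False-alarm press hazard (per second)
#'   outside the critical period, per state.
#' @param target_rate_gain Multiplier on the in-critical hazards when the
#'   target rate is 20 Hz rather than 30 Hz (must be >= 1).
#' @param seed Integer seed used by [simulate_session()] unless overridden.
#' @return An object of class `sim_params` (a named list).
#' @export
sim_params <- function(rt_median = 0.70,
                       rt_sigma_in = 0.10,
                       rt_sigma_out = 0.22,
                       omission_p_in = 0.05,
                       omission_p_out = 0.16,
                       commission_p_in = 0.03,
                       commission_p_out = 0.10,
                       state_dwell_mean = 30,
                       detect_hazard_in = 0.05,
                       detect_hazard_out = 0.15,
                       fa_hazard_in = 0.002,
                       fa_hazard_out = 0.008,
                       target_rate_gain = 1.3,
                       seed = NULL) {
  p <- list(rt_median = rt_median, rt_sigma_in = rt_sigma_in,
            rt_sigma_out = rt_sigma_out,
            omission_p_in = omission_p_in, omission_p_out = omission_p_out,
            commission_p_in = commission_p_in,
            commission_p_out = commission_p_out,
            state_dwell_mean = state_dwell_mean,
            detect_hazard_in = detect_hazard_in,
            detect_hazard_out = detect_hazard_out,
            fa_hazard_in = fa_hazard_in, fa_hazard_out = fa_hazard_out,
            target_rate_gain = target_rate_gain, seed = seed)
  probs <- c("omission_p_in", "omission_p_out", "commission_p_in",
             "commission_p_out")
  for (f in probs) {
    if (p[[f]] < 0 || p[[f]] > 1) {
      stop("`", f, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  hazards <- c("detect_hazard_in", "detect_hazard_out", "fa_hazard_in",
               "fa_hazard_out")
  for (f in hazards) {
    if (p[[f]] < 0) stop("`", f, "` must be >= 0", call. = FALSE)
  }
  if (p$rt_median <= 0 || p$rt_sigma_in <= 0 || p$rt_sigma_out <= 0) {
    stop("RT parameters must be positive", call. = FALSE)
  }
  if (p$state_dwell_mean < 1) {
    stop("`state_dwell_mean` must be >= 1", call. = FALSE)
  }
  if (p$target_rate_gain < 1) {
    stop("`target_rate_gain` must be >= 1", call. = FALSE)
  }
  structure(p, class = "sim_params")
}

#' Simulate the latent attentional-state chain
#'
#' Two-state Markov chain over trials with symmetric switching probability
#' `1 / state_dwell_mean` and a stationary start (each state with
#' probability 1/2). `state_dwell_mean = Inf` yields a constant state.
#'
#' @param n_trials Number of trials.
#' @param params A [sim_params()].
#' @param seed Optional integer seed; caller's RNG state is restored.
#' @return Character vector of `"in"` / `"out"` per trial.
#' @export
simulate_latent_states <- function(n_trials, params, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed, simulate_latent_states(n_trials, params, seed = NULL)))
  }
  p_switch <- 1 / params$state_dwell_mean
  s <- integer(n_trials)
  s[1] <- stats::rbinom(1, 1, 0.5)
  if (n_trials > 1) {
    flip <- stats::rbinom(n_trials - 1, 1, p_switch)
    s[-1] <- (s[1] + cumsum(flip)) %% 2
  }
  c("in", "out")[s + 1L]
}

# Truncated-lognormal RT sampler: inverse-CDF so draws are cheap and
# reproducible. Truncation keeps presses within onset + 1.04 s.
sample_rt <- function(n, rt_median, sigma, rt_max = 1.04) {
  if (n == 0) return(numeric(0))
  mu <- log(rt_median)
  f_hi <- stats::plnorm(rt_max, mu, sigma)
  stats::qlnorm(stats::runif(n) * f_hi, mu, sigma)
}

#' Simulate a full synthetic gradCPT session
#'
#' Draws a trial sequence, a critical-period onset and schedule, the latent
#' attentional-state chain, main-task presses (at most one per trial:
#' go trials press with probability `1 - omission_p_state` at onset +
#' truncated-lognormal RT; no-go trials press with probability
#' `commission_p_state`), and detection presses from the state- and
#' schedule-dependent Poisson hazards. Fully reproducible under a seed.
#'
#' @param cfg A [session_config()].
#' @param params A [sim_params()].
#' @param seed Integer seed; defaults to `params$seed`. `NULL` uses the
#'   current RNG stream.
#' @return A `session_events` list: `trials` (trial sequence plus latent
#'   `state` column), `schedule`, `main_presses`, `detect_presses`,
#'   `latent_state`, `cfg`, `params`.
#' @export
simulate_session <- function(cfg, params = sim_params(), seed = params$seed) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_session(cfg, params, seed = NULL)))
  }
  trials <- generate_trial_sequence(cfg)
  onset <- sample_critical_onset(cfg)
  sched <- build_critical_schedule(onset, cfg)
  state <- simulate_latent_states(cfg$n_trials, params)
  trials$state <- state

  # main-task presses
  is_out <- state == "out"
  p_press <- ifelse(trials$label == "go",
                    1 - ifelse(is_out, params$omission_p_out,
                               params$omission_p_in),
                    ifelse(is_out, params$commission_p_out,
                           params$commission_p_in))
  pressed <- stats::runif(cfg$n_trials) < p_press
  sigma <- ifelse(is_out, params$rt_sigma_out, params$rt_sigma_in)
  rt <- rep(NA_real_, cfg$n_trials)
  rt[pressed] <- vapply(which(pressed), function(i) {
    sample_rt(1, params$rt_median, sigma[i],
              rt_max = cfg$trial_duration +
                cfg$unambiguous_end_offset_into_next)
  }, numeric(1))
  main_presses <- sort(trials$onset[pressed] + rt[pressed])

  # detection presses: piecewise-constant hazard over time, switching at
  # the critical-window boundaries and at trial boundaries (where the
  # latent state can change)
  gain <- if (cfg$target_rate == 20) params$target_rate_gain else 1
  h_det <- gain * ifelse(is_out, params$detect_hazard_out,
                         params$detect_hazard_in)
  h_fa <- ifelse(is_out, params$fa_hazard_out, params$fa_hazard_in)
  a <- trials$onset
  b <- a + cfg$trial_duration
  ov_lo <- pmax(a, sched$critical_start)
  ov_hi <- pmin(b, sched$critical_end)
  len_in <- pmax(0, ov_hi - ov_lo)
  len_out <- pmax(0, cfg$trial_duration - len_in)
  n_in <- stats::rpois(cfg$n_trials, h_det * len_in)
  n_out <- stats::rpois(cfg$n_trials, h_fa * len_out)
  detect_presses <- unlist(lapply(seq_len(cfg$n_trials), function(i) {
    tt <- numeric(0)
    if (n_in[i] > 0) {
      tt <- stats::runif(n_in[i], ov_lo[i], ov_hi[i])
    }
    if (n_out[i] > 0) {
      # the non-critical part of a trial is at most one interval per side
      u <- stats::runif(n_out[i], 0, len_out[i])
      left <- max(0, min(ov_lo[i], b[i]) - a[i]) * (len_in[i] > 0)
      if (len_in[i] == 0) {
        tt <- c(tt, a[i] + u)
      } else {
        tt <- c(tt, ifelse(u < left, a[i] + u, ov_hi[i] + (u - left)))
      }
    }
    tt
  }), use.names = FALSE)
  detect_presses <- sort(detect_presses)

  structure(list(trials = trials,
                 schedule = sched,
                 main_presses = main_presses,
                 detect_presses = detect_presses,
                 latent_state = state,
                 cfg = cfg,
                 params = params),
            class = "session_events")
}

#' @export
print.session_events <- function(x, ...) {
  cat("gradCPT session:", nrow(x$trials), "trials,",
      length(x$main_presses), "main presses,",
      length(x$detect_presses), "detection presses; critical period [",
      signif(x$schedule$critical_start, 6), ",",
      signif(x$schedule$critical_end, 6), "] s\n")
  invisible(x)
}
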