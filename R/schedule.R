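#' Number of morph-weight updates per trial
#'
#' @param cfg A [session_config()].
#' @return Integer count of weight updates per trial
#'   (`trial_duration / morph_update_interval`), e.g. 32 for 800-ms trials
#'   updated every 25 ms.
#' @export
n_morph_steps <- function(cfg) {
  steps <- cfg$trial_duration / cfg$morph_update_interval
  if (abs(steps - round(steps)) > 1e-9) {
    stop("`trial_duration` is not an integer multiple of ",
         "`morph_update_interval`", call. = FALSE)
  }
  as.integer(round(steps))
}

#' Scene morph weight at a time point
#'
#' The scene of trial `trial` fades in linearly from 0 at its own onset to 1
#' at the onset of the next trial, then fades back to 0 by the end of that
#' next trial; at any instant the weights of the two temporally adjacent
#' scenes sum to 1. With `quantize = TRUE` (the display's behaviour) the
#' weight only changes at multiples of `morph_update_interval`, advancing by
#' `1 / n_morph_steps(cfg)` per update; with `quantize = FALSE` the
#' continuous linear envelope is returned. Note the classifier's 480-ms
#' landmark corresponds to a 60/40 morph on the linear envelope; on a 32-step
#' grid the nearest displayed weight is 19/32.
#'
#' @param t Time(s) in seconds from session start; vectorized.
#' @param trial 1-based trial index whose scene weight is requested.
#' @param cfg A [session_config()].
#' @param quantize Snap to the morph update grid? Default `TRUE`.
#' @return Weight(s) in `[0, 1]`.
#' @export
morph_weight <- function(t, trial, cfg, quantize = TRUE) {
  if (length(trial) != 1L || trial < 1L || trial > cfg$n_trials) {
    stop("`trial` out of range 1..", cfg$n_trials, call. = FALSE)
  }
  if (any(t < -1e-9 | t > cfg$session_duration + 1e-9)) {
    stop("`t` outside the session", call. = FALSE)
  }
  td <- cfg$trial_duration
  onset <- (trial - 1) * td
  rel <- t - onset
  if (quantize) {
    k <- n_morph_steps(cfg)
    rel <- floor(rel / cfg$morph_update_interval + 1e-9) / k * td
  }
  w <- ifelse(rel <= 0, 0,
       ifelse(rel <= td, rel / td,
       ifelse(rel <= 2 * td, 2 - rel / td, 0)))
  pmin(pmax(w, 0), 1)
}

#' Angular step of the peripheral dot per display frame
#'
#' The dot completes one revolution every `rotation_period` seconds at any
#' refresh rate, so lowering the rate enlarges the per-frame jump:
#' 1 degree/frame at 180 Hz, 6 at 30 Hz, 9 at 20 Hz (2-s rotation).
#'
#' @param rate Refresh rate, Hz.
#' @param rotation_period Rotation period, seconds.
#' @return Degrees advanced per frame.
#' @export
step_angle <- function(rate, rotation_period = 2) {
  if (any(!is.finite(rate)) || any(rate <= 0) ||
      !is.finite(rotation_period) || rotation_period <= 0) {
    stop("`rate` and `rotation_period` must be positive", call. = FALSE)
  }
  360 / (rate * rotation_period)
}

#' Build the critical-period refresh-rate schedule
#'
#' Constructs the piecewise-constant refresh-rate timeline: baseline until
#' `onset`, one half-rotation (`rotation_period / 2`) at each intermediate
#' ramp rate on the way down, `dwell_duration` at the target rate, the
#' mirrored ascending ramp, then baseline to the end of the session. With the
#' defaults this is a 4-s descent, 22-s dwell and 4-s return: a 30-s critical
#' period.
#'
#' @param onset Critical-period onset, seconds from session start. The whole
#'   critical window must fit inside
#'   `[onset_exclusion, session_duration - onset_exclusion]`.
#' @param cfg A [session_config()].
#' @return A `refresh_schedule`: list with `segments` (data.frame of
#'   `start_s`, `duration_s`, `rate_hz`), `critical_start`, `critical_end`,
#'   `target_rate`, `baseline_rate`.
#' @export
build_critical_schedule <- function(onset, cfg) {
  half <- cfg$rotation_period / 2
  ramp_total <- length(cfg$ramp_rates) * half
  crit_total <- 2 * ramp_total + cfg$dwell_duration
  lo <- cfg$onset_exclusion
  hi <- cfg$session_duration - cfg$onset_exclusion - crit_total
  if (onset < lo - 1e-9 || onset > hi + 1e-9) {
    stop("critical-period onset ", signif(onset, 6),
         " violates the exclusion zone [", lo, ", ", signif(hi, 6), "]",
         call. = FALSE)
  }
  rates <- c(cfg$baseline_rate,
             cfg$ramp_rates,
             cfg$target_rate,
             rev(cfg$ramp_rates),
             cfg$baseline_rate)
  durs <- c(onset,
            rep(half, length(cfg$ramp_rates)),
            cfg$dwell_duration,
            rep(half, length(cfg$ramp_rates)),
            cfg$session_duration - onset - crit_total)
  keep <- durs > 1e-12
  seg <- data.frame(start_s = cumsum(c(0, durs))[-(length(durs) + 1)][keep],
                    duration_s = durs[keep],
                    rate_hz = rates[keep])
  rownames(seg) <- NULL
  structure(list(segments = seg,
                 critical_start = onset,
                 critical_end = onset + crit_total,
                 target_rate = cfg$target_rate,
                 baseline_rate = cfg$baseline_rate),
            class = "refresh_schedule")
}

#' @export
print.refresh_schedule <- function(x, ...) {
  cat("refresh schedule:", nrow(x$segments), "segments; critical period [",
      signif(x$critical_start, 6), ",", signif(x$critical_end, 6), "] s at",
      x$target_rate, "Hz target\n")
  invisible(x)
}

#' Critical-period window of a schedule
#'
#' `which = "full"` returns the whole critical period (descending ramp, dwell
#' and ascending ramp); `which = "dwell"` returns only the interval spent at
#' the target rate, for sensitivity analyses that treat the ramps as
#' transitional.
#'
#' @param sched A `refresh_schedule`.
#' @param which `"full"` (default) or `"dwell"`.
#' @return `c(start, end)` in seconds.
#' @export
critical_window <- function(sched, which = c("full", "dwell")) {
  which <- match.arg(which)
  if (which == "full") {
    return(c(sched$critical_start, sched$critical_end))
  }
  seg <- sched$segments
  i <- which(seg$rate_hz == sched$target_rate &
               seg$start_s >= sched$critical_start - 1e-9)
  if (length(i) == 0) {
    return(c(sched$critical_start, sched$critical_start))
  }
  c(seg$start_s[i[1]], seg$start_s[i[1]] + seg$duration_s[i[1]])
}

#' Sample a critical-period onset
#'
#' Uniform draw over the feasible onsets: at least `onset_exclusion` seconds
#' after session start and early enough that the whole critical period ends
#' at least `onset_exclusion` seconds before session end.
#'
#' @param cfg A [session_config()].
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return Onset in seconds.
#' @export
sample_critical_onset <- function(cfg, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, sample_critical_onset(cfg, seed = NULL)))
  }
  half <- cfg$rotation_period / 2
  crit_total <- 2 * length(cfg$ramp_rates) * half + cfg$dwell_duration
  lo <- cfg$onset_exclusion
  hi <- cfg$session_duration - cfg$onset_exclusion - crit_total
  if (hi < lo) {
    stop("session too short: no feasible critical-period onset ",
         "(window [", lo, ", ", signif(hi, 6), "] is empty)", call. = FALSE)
  }
  stats::runif(1, lo, hi)
}

#' Generate the go/no-go trial sequence
#'
#' Places `n_nogo` no-go trials uniformly at random (without replacement)
#' among `n_trials` trials on the regular onset grid. Go trials carry the
#' city scene category, no-go trials the mountain category (the response
#' mapping used in the task). With `cfg$forbid_consecutive_nogo` the
#' placement is redrawn until no two no-go trials are adjacent.
#'
#' @param cfg A [session_config()].
#' @param seed Optional integer seed; caller's RNG state is restored.
#' @return data.frame with columns `trial`, `onset`, `label`
#'   (`"go"`/`"nogo"`), `scene_category` (`"city"`/`"mountain"`).
#' @export
generate_trial_sequence <- function(cfg, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_trial_sequence(cfg, seed = NULL)))
  }
  n <- cfg$n_trials
  label <- rep("go", n)
  if (cfg$n_nogo > 0) {
    repeat {
      pos <- sample.int(n, cfg$n_nogo)
      if (!cfg$forbid_consecutive_nogo || cfg$n_nogo < 2 ||
          all(diff(sort(pos)) > 1)) break
    }
    label[pos] <- "nogo"
  }
  data.frame(trial = seq_len(n),
             onset = (seq_len(n) - 1) * cfg$trial_duration,
             label = label,
             scene_category = ifelse(label == "go", "city", "mountain"))
}

#' Dot angle at a time point under a refresh schedule
#'
#' The dot's angle advances by [step_angle()] of the active segment's rate at
#' each of that segment's frame ticks (frames are spaced `1 / rate` seconds
#' from the segment start). Because the rotation period is rate-invariant,
#' the angle at every frame tick coincides with the continuous envelope
#' `360 / rotation_period * t` (mod 360): rate changes alter step size and
#' tick spacing, never phase.
#'
#' @param t Time(s) in seconds; vectorized.
#' @param sched A `refresh_schedule`.
#' @param cfg A [session_config()] (supplies `rotation_period`).
#' @return Angle(s) in degrees, `[0, 360)`.
#' @export
dot_angle_at <- function(t, sched, cfg) {
  seg <- sched$segments
  t_end <- seg$start_s[nrow(seg)] + seg$duration_s[nrow(seg)]
  if (any(t < -1e-9 | t > t_end + 1e-9)) {
    stop("`t` outside the schedule", call. = FALSE)
  }
  i <- findInterval(t + 1e-12, seg$start_s)
  i[i < 1L] <- 1L
  s0 <- seg$start_s[i]
  rate <- seg$rate_hz[i]
  ticks <- floor((t - s0) * rate + 1e-9)
  angle0 <- (360 / cfg$rotation_period * s0) %% 360
  (angle0 + ticks * step_angle(rate, cfg$rotation_period)) %% 360
}

#' Frame-tick stream for a schedule
#'
#' Enumerates every display frame tick of the schedule within `[from, to]`,
#' with the rate in force and the dot angle shown on that frame.
#'
#' @param sched A `refresh_schedule`.
#' @param cfg A [session_config()].
#' @param from,to Time range in seconds (defaults: whole schedule).
#' @return data.frame with `tick_time_s`, `rate_hz`, `dot_angle_deg`.
#' @export
frame_ticks <- function(sched, cfg, from = 0, to = NULL) {
  seg <- sched$segments
  if (is.null(to)) to <- seg$start_s[nrow(seg)] + seg$duration_s[nrow(seg)]
  out <- lapply(seq_len(nrow(seg)), function(i) {
    s0 <- seg$start_s[i]
    s1 <- s0 + seg$duration_s[i]
    n_frames <- ceiling(seg$duration_s[i] * seg$rate_hz[i] - 1e-9)
    tt <- s0 + (seq_len(n_frames) - 1) / seg$rate_hz[i]
    tt <- tt[tt >= from - 1e-12 & tt <= to + 1e-12 & tt < s1 - 1e-12]
    if (length(tt) == 0) return(NULL)
    data.frame(tick_time_s = tt, rate_hz = seg$rate_hz[i])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(tick_time_s = numeric(0), rate_hz = numeric(0),
                      dot_angle_deg = numeric(0)))
  }
  out$dot_angle_deg <- dot_angle_at(out$tick_time_s, sched, cfg)
  out
}

#' Write a schedule's segment table to CSV
#'
#' @param sched A `refresh_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(sched, path) {
  utils::write.csv(sched$segments, path, row.names = FALSE)
  invisible(path)
}
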