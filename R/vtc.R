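#' Per-trial RT series with gap interpolation
#'
#' The variance time course is computed from correct go responses only.
#' Every other trial (omissions, no-go trials whether or not a commission
#' occurred) receives the arithmetic mean of the nearest valid RT before and
#' after it; runs of consecutive gaps share the same bracketing neighbours.
#' Leading and trailing gaps take the single nearest valid RT.
#'
#' @param cs A `classified_session`.
#' @return List with `rt` (seconds per trial) and `interpolated_mask`
#'   (logical per trial, `TRUE` where the value was filled in).
#' @export
build_rt_series <- function(cs) {
  rt <- ifelse(cs$trials$outcome == "correct_go", cs$trials$rt, NA_real_)
  valid <- which(!is.na(rt))
  if (length(valid) < 2) {
    stop("need at least two correct go responses to build an RT series",
         call. = FALSE)
  }
  gaps <- which(is.na(rt))
  if (length(gaps) > 0) {
    idx_before <- findInterval(gaps, valid)           # 0 when none before
    before <- rep(NA_integer_, length(gaps))
    has_b <- idx_before >= 1L
    before[has_b] <- valid[idx_before[has_b]]
    after <- rep(NA_integer_, length(gaps))
    has_a <- idx_before < length(valid)
    after[has_a] <- valid[idx_before[has_a] + 1L]
    fill <- rowMeans(cbind(rt[before], rt[after]), na.rm = TRUE)
    rt[gaps] <- fill
  }
  list(rt = rt, interpolated_mask = is.na(
    ifelse(cs$trials$outcome == "correct_go", cs$trials$rt, NA_real_)))
}

#' Raw variance time course: absolute z-scored RTs
#'
#' Both extremes index lapses — very slow RTs reflect sluggish evidence
#' accumulation, very fast ones impulsive responding — so the deviation is
#' the absolute z-score. The z-score uses the population (1/n) standard
#' deviation; the downstream median split is invariant to that choice.
#'
#' @param rts Numeric per-trial RT series (finite).
#' @return Non-negative deviation per trial; all zeros if the series is
#'   constant.
#' @export
compute_vtc <- function(rts) {
  if (any(!is.finite(rts))) stop("`rts` must be finite", call. = FALSE)
  m <- mean(rts)
  s <- sqrt(mean((rts - m)^2))
  if (s == 0) return(rep(0, length(rts)))
  abs((rts - m) / s)
}

#' Gaussian smoothing kernel used for the VTC
#'
#' Gaussian weights with `sigma = fwhm / (2 * sqrt(2 * log(2)))`, truncated
#' to lags `-radius..radius` and renormalized to sum to one. With the
#' defaults (FWHM 9 trials, radius 10) the kernel spans 21 taps: the centre
#' trial plus the surrounding 20 trials.
#'
#' @param fwhm Full width at half maximum, in trials.
#' @param radius Truncation radius, in trials.
#' @return Numeric vector of `2 * radius + 1` weights summing to 1.
#' @export
vtc_kernel <- function(fwhm = 9, radius = 10) {
  if (fwhm <= 0) stop("`fwhm` must be positive", call. = FALSE)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w <- stats::dnorm(seq(-radius, radius), 0, sigma)
  w / sum(w)
}

#' Smooth a per-trial series with the truncated Gaussian kernel
#'
#' Near the series edges the kernel is re-truncated to the available trials
#' and renormalized, so no values are fabricated outside the session and the
#' effective weights always sum to one.
#'
#' @param raw Numeric per-trial series.
#' @param fwhm Full width at half maximum, trials.
#' @param radius Truncation radius, trials.
#' @return Smoothed series, same length as `raw`.
#' @export
smooth_vtc <- function(raw, fwhm = 9, radius = 10) {
  w <- vtc_kernel(fwhm, radius)
  n <- length(raw)
  num <- numeric(n)
  den <- numeric(n)
  for (lag in seq(-radius, radius)) {
    wk <- w[lag + radius + 1]
    src <- seq_len(n) + lag
    ok <- src >= 1 & src <= n
    num[ok] <- num[ok] + wk * raw[src[ok]]
    den[ok] <- den[ok] + wk
  }
  num / den
}

#' Median split of the smoothed VTC into attentional-state epochs
#'
#' Trials at or below the sample median of the smoothed VTC are labelled
#' in-the-zone (low variability), the rest out-of-the-zone. Ties go to
#' in-the-zone; with continuous-valued input exactly `ceiling(n / 2)`
#' trials land in the zone.
#'
#' @param smoothed Numeric series.
#' @return List with `median` and `state` (`"in"`/`"out"` per trial).
#' @export
median_split <- function(smoothed) {
  if (length(smoothed) == 0) stop("empty series", call. = FALSE)
  med <- stats::median(smoothed)
  list(median = med, state = ifelse(smoothed <= med, "in", "out"))
}

#' Full variance-time-course analysis of a classified session
#'
#' Builds the interpolated RT series, z-scores it, smooths with the
#' FWHM-`fwhm` Gaussian kernel and median-splits the result into
#' in/out-of-the-zone epochs.
#'
#' @param cs A `classified_session`.
#' @param fwhm Smoothing kernel FWHM in trials.
#' @param radius Kernel truncation radius in trials.
#' @return A `vtc_result`: list with `raw_deviation`, `smoothed`, `median`,
#'   `state`, `interpolated_mask`, `fwhm`.
#' @export
run_vtc <- function(cs, fwhm = 9, radius = 10) {
  series <- build_rt_series(cs)
  raw <- compute_vtc(series$rt)
  smoothed <- smooth_vtc(raw, fwhm = fwhm, radius = radius)
  split <- median_split(smoothed)
  structure(list(raw_deviation = raw,
                 smoothed = smoothed,
                 median = split$median,
                 state = split$state,
                 interpolated_mask = series$interpolated_mask,
                 fwhm = fwhm),
            class = "vtc_result")
}

#' @export
print.vtc_result <- function(x, ...) {
  cat("VTC over", length(x$smoothed), "trials: median",
      signif(x$median, 4), ";", sum(x$state == "in"), "in-the-zone /",
      sum(x$state == "out"), "out-of-the-zone;",
      sum(x$interpolated_mask), "interpolated trials\n")
  invisible(x)
}

#' Proportion of in-the-zone trials in a time window
#'
#' @param result A `vtc_result`.
#' @param window `c(start, end)` seconds, inclusive; trials count when their
#'   onset lies inside.
#' @param cfg A [session_config()] (supplies the trial onset grid).
#' @return Fraction in `[0, 1]`, or `NA` (with a warning) if no trial onset
#'   falls in the window.
#' @export
in_zone_proportion <- function(result, window, cfg) {
  onsets <- (seq_along(result$state) - 1) * cfg$trial_duration
  sel <- onsets >= window[1] - 1e-9 & onsets <= window[2] + 1e-9
  if (!any(sel)) {
    warning("no trial onset inside the window; proportion undefined")
    return(NA_real_)
  }
  mean(result$state[sel] == "in")
}

#' Write the per-trial VTC table
#'
#' @param result A `vtc_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_vtc_table <- function(result, path) {
  utils::write.csv(
    data.frame(trial = seq_along(result$smoothed),
               raw_deviation = result$raw_deviation,
               smoothed = result$smoothed,
               state = result$state,
               interpolated = result$interpolated_mask),
    path, row.names = FALSE)
  invisible(path)
}
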