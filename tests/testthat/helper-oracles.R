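# Independent reference implementations used as test oracles. These are
# deliberately naive (per-element loops, explicit scans) and share no code
# with the package internals.

# Brute-force press resolver: scans every trial's window per press, then
# applies the written ambiguity rules one press at a time.
oracle_assign <- function(trials, presses, cfg) {
  n <- nrow(trials)
  td <- cfg$trial_duration
  lo <- cfg$unambiguous_start_offset
  hi <- cfg$trial_duration + cfg$unambiguous_end_offset_into_next
  cutoff <- cfg$assignment_cutoff
  eps <- 1e-9
  assigned <- rep(NA_real_, n)
  discarded <- numeric(0)

  give <- function(k, p) {
    if (is.na(assigned[k])) assigned[k] <<- p
    else discarded <<- c(discarded, p)
  }

  # stage 1: full scan of all windows for each press
  ambiguous <- numeric(0)
  for (p in presses) {
    owner <- NA
    for (k in seq_len(n)) {
      w1 <- trials$onset[k] + lo
      w2 <- trials$onset[k] + hi
      if (p >= w1 - eps && p < w2 - eps) owner <- k
    }
    if (is.na(owner)) ambiguous <- c(ambiguous, p) else give(owner, p)
  }

  # stage 2: rule order (no-response) -> (go preference) -> (480-ms cutoff)
  for (p in ambiguous) {
    curr <- NA
    for (k in seq_len(n)) {
      if (p >= trials$onset[k] - eps && p < trials$onset[k] + td - eps) {
        curr <- k
      }
    }
    if (is.na(curr)) curr <- n     # p at/after the last trial's end
    if (curr == 1) {
      if (is.na(assigned[1])) give(1, p) else discarded <- c(discarded, p)
      next
    }
    prev <- curr - 1
    prev_free <- is.na(assigned[prev])
    curr_free <- is.na(assigned[curr])
    if (prev_free != curr_free) {
      give(if (prev_free) prev else curr, p)
    } else if (trials$label[prev] != trials$label[curr]) {
      give(if (trials$label[prev] == "go") prev else curr, p)
    } else if (p - trials$onset[curr] <= cutoff + eps) {
      give(prev, p)
    } else {
      give(curr, p)
    }
  }
  list(press_time = assigned, discarded = sort(discarded))
}

# Naive gap filler: for each invalid trial scan outward for the nearest
# valid RT on each side and average whatever exists.
oracle_fill_gaps <- function(rt) {
  out <- rt
  for (i in seq_along(rt)) {
    if (!is.na(rt[i])) next
    left <- NA
    for (j in rev(seq_len(i - 1))) {
      if (!is.na(rt[j])) { left <- rt[j]; break }
    }
    right <- NA
    for (j in seq(i + 1, length(rt), length.out = max(0, length(rt) - i))) {
      if (!is.na(rt[j])) { right <- rt[j]; break }
    }
    out[i] <- mean(c(left, right), na.rm = TRUE)
  }
  out
}

# Stratified Monte-Carlo estimate of the JZS marginal likelihood: average
# of the noncentral-t likelihood over draws from the Cauchy prior, taken at
# stratified prior quantiles so the estimator's error is far below the
# comparison tolerance.
oracle_mc_bf <- function(t_stat, n, cauchy_scale = sqrt(2) / 2,
                         n_draws = 1e6) {
  u <- (seq_len(n_draws) - runif(n_draws)) / n_draws
  delta <- cauchy_scale * tan(pi * (u - 0.5))
  marg <- mean(suppressWarnings(
    dt(t_stat, n - 1, ncp = delta * sqrt(n))))
  marg / dt(t_stat, n - 1)
}
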