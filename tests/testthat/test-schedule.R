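cfg <- session_config()

test_that("morph stepping: 32 updates per 800-ms trial, degenerate cases", {
  expect_identical(n_morph_steps(cfg), 32L)
  expect_identical(n_morph_steps(session_config(morph_update_interval = 0.05)),
                   16L)
  expect_identical(n_morph_steps(session_config(morph_update_interval = 0.8)),
                   1L)
})

test_that("morph weight rises 0 to 1 over a trial and is 60/40 at 480 ms", {
  on10 <- (10 - 1) * cfg$trial_duration
  expect_equal(morph_weight(on10, 10, cfg), 0)
  expect_equal(morph_weight(on10 + 0.8, 10, cfg), 1)
  # linear envelope hits the 60/40 landmark exactly ...
  expect_equal(morph_weight(on10 + 0.480, 10, cfg, quantize = FALSE), 0.60)
  expect_equal(morph_weight(on10 + 0.480, 9, cfg, quantize = FALSE), 0.40)
  # ... the 32-step display grid lands within half a step of it
  expect_equal(morph_weight(on10 + 0.480, 10, cfg), 19 / 32)
  expect_lt(abs(morph_weight(on10 + 0.480, 10, cfg) - 0.60), 1 / 32)
  expect_error(morph_weight(1, 0, cfg), "out of range")
  expect_error(morph_weight(1, 601, cfg), "out of range")
})

test_that("adjacent scene weights sum to one on the whole update grid", {
  grid <- seq(0, 2 * cfg$trial_duration, by = cfg$morph_update_interval)
  on10 <- (10 - 1) * cfg$trial_duration
  for (q in c(TRUE, FALSE)) {
    w_curr <- morph_weight(on10 + grid[grid <= 0.8], 10, cfg, quantize = q)
    w_prev <- morph_weight(on10 + grid[grid <= 0.8], 9, cfg, quantize = q)
    expect_equal(w_curr + w_prev, rep(1, sum(grid <= 0.8)),
                 tolerance = 1e-12)
  }
})

test_that("step angle: 1 degree at 180 Hz, 6 at 30 Hz, 9 at 20 Hz", {
  expect_equal(step_angle(180, 2), 1)
  expect_equal(step_angle(30, 2), 6)
  expect_equal(step_angle(20, 2), 9)
  expect_error(step_angle(0), "positive")
  expect_error(step_angle(60, -1), "positive")
})

test_that("critical schedule: ramp structure, 30-s window, symmetry", {
  sched <- build_critical_schedule(200, cfg)
  expect_equal(sched$critical_end - sched$critical_start, 30)
  seg <- sched$segments
  # contiguous, non-overlapping, covering the session
  expect_equal(seg$start_s[-1], head(seg$start_s + seg$duration_s, -1))
  expect_equal(sum(seg$duration_s), cfg$session_duration)
  # exactly one target-rate segment, dwell length 22 s
  tgt <- seg[seg$rate_hz == cfg$target_rate, ]
  expect_identical(nrow(tgt), 1L)
  expect_equal(tgt$duration_s, 22)
  # baseline everywhere outside the critical window
  outside <- seg$start_s + seg$duration_s <= sched$critical_start + 1e-9 |
    seg$start_s >= sched$critical_end - 1e-9
  expect_true(all(seg$rate_hz[outside] == cfg$baseline_rate))
  # each ramp step is one half rotation (1 s); 4-s descending ramp
  down <- seg[seg$rate_hz %in% cfg$ramp_rates &
                seg$start_s < tgt$start_s, ]
  up <- seg[seg$rate_hz %in% cfg$ramp_rates & seg$start_s > tgt$start_s, ]
  expect_equal(down$duration_s, rep(cfg$rotation_period / 2, 4))
  expect_equal(down$rate_hz, c(90, 60, 45, 36))
  expect_equal(sum(up$duration_s), 4)
  # mirrored ascent: same (rate, duration) multiset, inverse order
  expect_equal(up$rate_hz, rev(down$rate_hz))
  expect_equal(up$duration_s, rev(down$duration_s))
})

test_that("degenerate schedule with no ramp and no dwell collapses", {
  cfg0 <- session_config(ramp_rates = numeric(0), dwell_duration = 0)
  sched <- build_critical_schedule(100, cfg0)
  expect_equal(sched$critical_end, sched$critical_start)
  expect_true(all(sched$segments$rate_hz == cfg0$baseline_rate))
})

test_that("onset constraint errors and dwell-window accessor", {
  expect_error(build_critical_schedule(10, cfg), "exclusion")
  expect_error(build_critical_schedule(395, cfg), "exclusion")
  sched <- build_critical_schedule(200, cfg)
  dw <- critical_window(sched, "dwell")
  expect_equal(dw, c(204, 226))
  expect_equal(critical_window(sched, "full"), c(200, 230))
})

test_that("critical onset sampler respects bounds and is reproducible", {
  draws <- withr::with_seed(99, replicate(1e4, sample_critical_onset(cfg)))
  expect_true(all(draws >= 60 & draws <= 390))
  expect_gt(diff(range(draws)), 300)  # actually spans the feasible window
  expect_identical(sample_critical_onset(cfg, seed = 5),
                   sample_critical_onset(cfg, seed = 5))
  short <- session_config(session_duration = 144, n_trials = 180,
                          n_go = 162, n_nogo = 18)
  expect_error(sample_critical_onset(short), "feasible")
})

test_that("trial sequence has the configured label counts on the grid", {
  tr <- generate_trial_sequence(cfg, seed = 3)
  expect_identical(nrow(tr), 600L)
  expect_identical(sum(tr$label == "nogo"), 60L)
  expect_identical(sum(tr$label == "go"), 540L)
  expect_equal(tr$onset, (0:599) * 0.8)
  expect_true(all(tr$scene_category[tr$label == "go"] == "city"))
  # all-go degenerate case
  allgo <- session_config(n_go = 600, n_nogo = 0)
  expect_true(all(generate_trial_sequence(allgo, seed = 1)$label == "go"))
  # no-adjacent-no-go variant
  cfg2 <- session_config(forbid_consecutive_nogo = TRUE)
  pos <- which(generate_trial_sequence(cfg2, seed = 8)$label == "nogo")
  expect_true(all(diff(pos) > 1))
})

test_that("dot kinematics: half cycle per second, full cycle per period", {
  sched <- build_critical_schedule(200, cfg)
  a0 <- dot_angle_at(0, sched, cfg)
  expect_equal(dot_angle_at(2, sched, cfg), a0)
  expect_equal((dot_angle_at(1, sched, cfg) - a0) %% 360, 180)
})

test_that("quantized dot angle equals the continuous envelope at every tick", {
  # rate changes alter step size and tick spacing, never phase
  cfg30 <- session_config(dwell_duration = 22)
  sched <- build_critical_schedule(171.3, cfg30)
  ticks <- frame_ticks(sched, cfg30, from = 165, to = 210)
  expect_true(all(ticks$rate_hz[ticks$tick_time_s > 176 &
                                  ticks$tick_time_s < 197] == 30))
  envelope <- (360 / cfg30$rotation_period * ticks$tick_time_s) %% 360
  expect_equal(ticks$dot_angle_deg, envelope, tolerance = 1e-9)
  expect_error(dot_angle_at(-1, sched, cfg30), "outside")
  expect_error(dot_angle_at(481, sched, cfg30), "outside")
})

test_that("frame tick spacing follows the active segment's rate", {
  sched <- build_critical_schedule(200, cfg)
  ticks <- frame_ticks(sched, cfg, from = 205, to = 225)
  expect_equal(unique(ticks$rate_hz), cfg$target_rate)
  expect_equal(diff(ticks$tick_time_s),
               rep(1 / cfg$target_rate, nrow(ticks) - 1),
               tolerance = 1e-9)
})
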