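cfg <- session_config()

test_that("unambiguous window is [onset + 480 ms, next onset + 240 ms)", {
  w <- unambiguous_window(1, cfg)
  expect_equal(unname(w), c(0.480, 1.040))
  expect_equal(unname(diff(w)), 0.560)
  # original-variant offsets, shifted 80 ms later, keep the 560-ms length
  orig <- session_config(unambiguous_start_offset = 0.560,
                         unambiguous_end_offset_into_next = 0.320)
  w2 <- unambiguous_window(1, orig)
  expect_equal(unname(w2), c(0.560, 1.120))
  expect_equal(unname(diff(w2)), 0.560)
})

test_that("unambiguous press scores correct_go with its RT", {
  ses <- manual_session(c("go", "go", "go"), 0.8 + 0.500)
  cs <- assign_presses(ses, ses$cfg)
  expect_identical(cs$trials$outcome[2], "correct_go")
  expect_identical(cs$trials$provenance[2], "unambiguous")
  expect_equal(cs$trials$rt[2], 0.500)
  expect_equal(cs$ambiguous_fraction, 0)
})

test_that("ambiguity rules resolve in the written order", {
  td <- 0.8
  # rule (a): prev occupied, current free -> current takes the press
  ses <- manual_session(c("go", "go", "go"),
                        c(0.6, td + 0.300))  # 0.6 unambiguous on trial 1
  cs <- assign_presses(ses, ses$cfg)
  expect_equal(cs$trials$press_time[2], td + 0.300)
  expect_identical(cs$trials$provenance[2], "reassigned_no_response")

  # rule (b): both free, labels differ -> go trial wins
  ses <- manual_session(c("nogo", "go", "go"), td + 0.300)
  cs <- assign_presses(ses, ses$cfg)
  expect_identical(cs$trials$outcome[2], "correct_go")
  expect_identical(cs$trials$provenance[2], "reassigned_go")
  ses <- manual_session(c("go", "nogo", "go"), td + 0.300)
  cs <- assign_presses(ses, ses$cfg)
  expect_identical(cs$trials$provenance[1], "reassigned_go")
  expect_identical(cs$trials$outcome[2], "correct_nogo")

  # rule (c): same labels, both free; <= 480 ms -> previous trial
  ses <- manual_session(c("go", "go", "go"), td + 0.300)
  cs <- assign_presses(ses, ses$cfg)
  expect_identical(cs$trials$provenance[1], "reassigned_cutoff_prev")
  expect_equal(cs$trials$rt[1], td + 0.300)

  # first trial has no previous: press in its opening band stays with it
  ses <- manual_session(c("go", "go"), 0.100)
  cs <- assign_presses(ses, ses$cfg)
  expect_equal(cs$trials$press_time[1], 0.100)

  # surplus press on an occupied trial is discarded
  ses <- manual_session(c("go", "go"), c(0.50, 0.60))
  cs <- assign_presses(ses, ses$cfg)
  expect_equal(cs$trials$press_time[1], 0.50)
  expect_equal(cs$discarded, 0.60)
})

test_that("classifier agrees with the brute-force oracle on random instances", {
  withr::local_seed(1234)
  for (i in 1:1000) {
    inst <- random_instance()
    cs <- assign_presses(inst, inst$cfg)
    orc <- oracle_assign(inst$trials, inst$main_presses, inst$cfg)
    expect_equal(cs$trials$press_time, orc$press_time)
    expect_equal(sort(cs$discarded), orc$discarded)
  }
})

test_that("press conservation and outcome bookkeeping hold on simulations", {
  for (seed in 1:5) {
    ev <- simulate_session(cfg, sim_params(), seed = seed)
    cs <- assign_presses(ev)
    assigned <- sum(!is.na(cs$trials$press_time))
    expect_identical(assigned + length(cs$discarded), cs$n_presses)
    tab <- table(factor(cs$trials$outcome,
                        c("correct_go", "omission", "correct_nogo",
                          "commission")))
    expect_identical(unname(tab[["correct_go"]] + tab[["omission"]]),
                     as.integer(cfg$n_go))
    expect_identical(unname(tab[["correct_nogo"]] + tab[["commission"]]),
                     as.integer(cfg$n_nogo))
    expect_true(cs$ambiguous_fraction >= 0 && cs$ambiguous_fraction <= 1)
  }
})

test_that("unsorted presses are rejected", {
  ses <- manual_session(c("go", "go"), c(0.5, 0.6))
  ses$main_presses <- c(0.6, 0.5)
  expect_error(assign_presses(ses, ses$cfg), "sorted")
})

test_that("windowed accuracy is a simple percent of correct trials", {
  cs <- manual_classified(
    c(rep("correct_go", 8), "omission", "correct_nogo"),
    c(rep(0.6, 8), NA, NA))
  expect_equal(accuracy_in_window(cs, c(0, 10 * 0.8)), 90)
  expect_equal(accuracy_in_window(cs, c(0, 0.79)), 100)
  expect_warning(out <- accuracy_in_window(cs, c(100, 101)), "undefined")
  expect_true(is.na(out))
})

test_that("error rates split correctly by state and error type", {
  outcome <- c(rep("correct_go", 6), "omission", "omission",
               rep("correct_nogo", 8), "commission", "commission")
  rt <- ifelse(outcome == "correct_go", 0.6, NA)
  cs <- manual_classified(outcome, rt)
  epochs <- list(state = c(rep("in", 8), rep("out", 10)))
  er <- error_rates_by_state(cs, epochs)
  # in: 6 go + 2 omissions? no — first 8 trials are go (6 correct, 2 om)
  expect_equal(er$rate[er$error_type == "omission" & er$state == "in"],
               2 / 8)
  expect_equal(er$rate[er$error_type == "commission" & er$state == "out"],
               2 / 10)
  # no go trials in "out": omission rate undefined there
  expect_true(is.na(er$rate[er$error_type == "omission" &
                              er$state == "out"]))
  # perfect session: all defined rates are zero
  cs2 <- manual_classified(c(rep("correct_go", 5), rep("correct_nogo", 5)),
                           c(rep(0.6, 5), rep(NA, 5)))
  er2 <- error_rates_by_state(cs2, list(state = rep(c("in", "out"), 5)))
  expect_true(all(er2$rate[!is.na(er2$rate)] == 0))
  expect_error(error_rates_by_state(cs2, list(state = "in")), "every trial")
})
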