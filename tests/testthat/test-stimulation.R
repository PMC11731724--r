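test_that("opsin current follows the piecewise form with fixed reversals", {
  expect_equal(opto_current(0, seq(-90, 10, by = 10)), rep(0, 11))
  expect_equal(opto_current(0.1, -60), 0.1 * (-60 - 0))     # = -6
  expect_equal(opto_current(-0.5, -60), -(-0.5) * (-60 + 400))  # = 170
  # zero exactly at each opsin's reversal potential
  expect_equal(opto_current(0.3, 0), 0)
  expect_equal(opto_current(-0.3, -400), 0)
  # vectorized over conductances
  expect_equal(opto_current(c(0.1, -0.5), c(-60, -60)), c(-6, 170))
})

test_that("stop drive increments the external AMPA frequency", {
  expect_equal(stop_drive(3, 0), 3)
  expect_equal(stop_drive(c(3, 5), 0.6), c(3.6, 5.6))
  expect_error(stop_drive(0.3, -1), "negative")
})

test_that("trial scheduling: fractions, explicit lists, bounds", {
  expect_equal(schedule_trials(1.0, 7), 0:6)
  expect_equal(schedule_trials(0.0, 7), integer(0))
  expect_equal(schedule_trials(list(2, 3, 6), 10), c(2L, 3L, 6L))
  set.seed(9)
  half <- schedule_trials(0.5, 10)
  expect_equal(length(half), 5)
  expect_true(all(half >= 0 & half <= 9) && !anyDuplicated(half))
  expect_error(schedule_trials(list(11), 10), "out of range")
})

test_that("channel targeting: all, any, explicit label", {
  ch <- c("a", "b", "c")
  all3 <- resolve_targets("all", ch, 4)
  expect_true(all(vapply(all3, identical, logical(1), ch)))
  named <- resolve_targets("a", ch, 3)
  expect_true(all(unlist(named) == "a"))
  set.seed(12)
  any1 <- unlist(resolve_targets("any", ch, 900))
  tb <- table(any1) / 900
  expect_true(all(abs(tb - 1 / 3) < 3 * sqrt(2 / 9 / 900)))
  expect_error(resolve_targets("up", ch, 2), "unknown stimulation channel")
})

test_that("recorded stimulation covers exactly the scheduled trials/windows", {
  fx <- tiny_cfg(seed = 51, n_trials = 3,
                 opt_signal_present = list(TRUE),
                 opt_signal_probability = list(list(1)),  # trial 1 only
                 opt_signal_amplitude = list(0.2),
                 opt_signal_onset = list(10),
                 opt_signal_duration = list(50),
                 opt_signal_channel = list("left"),
                 opt_signal_population = list("iSPN"),
                 record_variables = c("optogenetic_input"))
  r <- run_tiny(fx)[[1]]
  rec <- r$recordings$optogenetic_input
  expect_equal(nrow(rec), 1)
  expect_equal(rec$trial, 1)
  expect_equal(rec$population, "iSPN")
  expect_equal(rec$channel, "left")
  expect_equal(rec$amplitude, 0.2)
  expect_equal(rec$offset_ms - rec$onset_ms, 50, tolerance = 0.2)
  expect_false(r$datatables$opto_applied[1])
  expect_true(r$datatables$opto_applied[2])
  expect_false(r$datatables$opto_applied[3])
})

test_that("phase-named durations span exactly the realized phase", {
  fx <- tiny_cfg(seed = 61, n_trials = 2,
                 opt_signal_present = list(TRUE),
                 opt_signal_probability = list(1.0),
                 opt_signal_amplitude = list(0.05),
                 opt_signal_onset = list(0),
                 opt_signal_duration = list("phase 1"),
                 opt_signal_channel = list("all"),
                 opt_signal_population = list("Cx"),
                 record_variables = c("optogenetic_input"))
  r <- run_tiny(fx)[[1]]
  rec <- r$recordings$optogenetic_input
  dt <- r$datatables
  for (i in seq_len(nrow(rec))) {
    tr <- rec$trial[i]
    expect_equal(rec$offset_ms[i] - rec$onset_ms[i],
                 dt$phase1_ms[dt$trial == tr], tolerance = 0.2)
  }
})

test_that("strong stop protocols increase the fraction of stopped trials", {
  mk <- function(present) list(
    experimentchoice = "stop-signal", seed = 0, n_trials = 6,
    channels = "left", number_of_choices = 1, conflict = 1.0,
    volatility = list(NULL, "exact"), reward_std = 0, maxstim = 1.0,
    stop_signal_present = list(present, present),
    stop_signal_probability = list(1.0, 1.0),
    stop_signal_amplitude = list(2.0, 2.0),
    stop_signal_onset = list(30, 60),
    stop_signal_duration = list(145, 145),
    stop_signal_channel = list("all", "all"),
    stop_signal_population = list("STN", "GPeA"))
  fx <- make_fixture_network("small", seed = 0, task = "stop-signal")
  none_frac <- function(present) {
    n <- 0; tot <- 0
    for (s in c(71, 72)) {
      cfg <- mk(present); cfg$seed <- s
      r <- run_simulations(cfg, paramfile = fx$paramfile)[[1]]
      n <- n + sum(r$datatables$decision == "none")
      tot <- tot + nrow(r$datatables)
    }
    n / tot
  }
  expect_gt(none_frac(TRUE), none_frac(FALSE))
})
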