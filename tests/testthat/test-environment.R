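test_that("reward schedules follow conflict, volatility and change points", {
  s <- generate_reward_schedule(c(1, 0), list(NULL, "exact"), 1)
  expect_equal(unname(s$prob[1, ]), c(1, 0))
  expect_equal(s$optimal[1], 1)

  # Fig-5-style switching: lambda = 10 exact over 40 trials -> 10, 20, 30
  s <- generate_reward_schedule(c(0.8, 0.2), list(10, "exact"), 40)
  expect_equal(s$change_points, c(10L, 20L, 30L))
  expect_equal(unname(s$prob[10, ]), c(0.8, 0.2))   # trial 9 (0-based)
  expect_equal(unname(s$prob[11, ]), c(0.2, 0.8))   # switched at trial 10
  expect_equal(diff(c(0, s$change_points)), rep(10, 3))

  # binary rewards: sd 0, mean 1 -> delivered magnitude exactly 1
  s <- generate_reward_schedule(c(1, 1), list(NULL, "exact"), 1,
                                reward_mu = 1, reward_std = 0)
  set.seed(1)
  expect_equal(replicate(20, cbgt:::draw_reward(s, 0, 1)), rep(1, 20))

  expect_error(generate_reward_schedule(c(0.5, 0.5), list(0, "exact"), 10),
               "cannot be 0")
  expect_error(generate_reward_schedule(c(0.5, 0.5), list(10, "exact"), 10),
               "cannot be 0|total number")
  expect_error(generate_reward_schedule(c(1.5, 0), list(NULL, "exact"), 1),
               "\\[0,1\\]")
})

test_that("cyclic rotation handles more than two actions", {
  s <- generate_reward_schedule(c(1.0, 0.5, 0.2), list(2, "exact"), 6)
  expect_equal(unname(s$prob[1, ]), c(1.0, 0.5, 0.2))
  expect_equal(unname(s$prob[3, ]), c(0.5, 0.2, 1.0))
  expect_equal(unname(s$prob[5, ]), c(0.2, 1.0, 0.5))
})

test_that("poisson volatility draws gaps averaging lambda, never below 1", {
  set.seed(3)
  gaps <- unlist(lapply(1:300, function(i) {
    s <- generate_reward_schedule(c(0.7, 0.3), list(5, "poisson"), 60)
    diff(c(0, s$change_points))
  }))
  expect_true(all(gaps >= 1))
  expect_equal(mean(gaps), 5, tolerance = 0.1)
})

test_that("ramp recursion matches its closed form", {
  expect_equal(ramp_update(0, 1), 0.1)
  expect_equal(ramp_update(0.7, 0.7), 0.7)  # fixed point
  # from 0 with constant target: after k steps, I_target (1 - 0.9^k)
  target <- 2.5
  x <- 0
  for (k in 1:25) {
    x <- ramp_update(x, target)
    expect_equal(x, target * (1 - 0.9^k), tolerance = 1e-12)
  }
})

test_that("decision boundary rule: first crossing, ties, timeout", {
  d <- check_decision(c(31, 12), threshold = 30, elapsed = 180,
                      max_wait = 1000)
  expect_equal(d$event, "decision")
  expect_equal(d$channel, 1)
  expect_equal(d$time, 180)

  expect_equal(check_decision(c(10, 20), 30, 400, 1000)$event, "continue")
  to <- check_decision(c(10, 20), 30, 1000, 1000)
  expect_equal(to$event, "timeout")
  expect_true(is.na(to$channel))

  # simultaneous crossings: the higher rate wins
  expect_equal(check_decision(c(31, 33), 30, 50, 1000)$channel, 2)
  # exact ties break uniformly at random
  set.seed(5)
  wins <- replicate(400, check_decision(c(35, 35), 30, 50, 1000)$channel)
  expect_true(abs(mean(wins == 1) - 0.5) < 0.1)
  expect_error(check_decision(c(-1, 5), 30, 10, 100), "rates")
})

test_that("movement times follow the configured distribution", {
  expect_equal(sample_movement_time(list("constant", 300), 50), rep(300, 50))
  set.seed(2)
  d <- sample_movement_time(NULL, 1e4)
  expect_equal(mean(d), 250, tolerance = 0.0005)   # +-3 SEM ~ 0.045 ms
  expect_equal(sd(d), 1.5, tolerance = 0.03)
  m <- sample_movement_time(list("mean", 100), 5e3)
  expect_equal(mean(m), 100, tolerance = 0.001)
  expect_true(all(m > 0))
  expect_error(sample_movement_time(list("constant", -5)), "positive")
  expect_error(sample_movement_time(list("bogus", 10)), "movement_time")
})

test_that("trial phases: consolidation and reset durations are as configured", {
  fx <- tiny_cfg(seed = 21, n_trials = 2, movement_time = list("constant", 300))
  r <- run_tiny(fx)[[1]]
  dt <- r$datatables
  decided <- dt[dt$decision != "none", ]
  expect_gt(nrow(decided), 0)
  expect_equal(decided$phase1_ms, rep(300, nrow(decided)))
  expect_equal(dt$phase2_ms, rep(600, 2))
  expect_true(all(dt$decision_time <= 1000, na.rm = TRUE))
  expect_true(all(dt$reward[dt$decision == "none"] == 0))
})

test_that("per-channel selection is at chance with symmetric weights", {
  # pooled over seeds; plasticity off, equal conflict entries
  counts <- c(left = 0, right = 0, none = 0)
  for (s in c(101, 202, 303)) {
    fx <- tiny_cfg(seed = s, n_trials = 8)
    dt <- run_tiny(fx)[[1]]$datatables
    tb <- table(factor(dt$decision, levels = names(counts)))
    counts <- counts + as.numeric(tb)
  }
  n_dec <- counts[["left"]] + counts[["right"]]
  expect_gt(n_dec, 10)
  ci <- qbinom(c(0.005, 0.995), n_dec, 0.5)
  expect_true(counts[["left"]] >= ci[1] && counts[["left"]] <= ci[2])
})
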