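test_that("Q updates follow the delta rule", {
  q <- c(left = 0.5, right = 0.5)
  # reward equal to the current value: fixed point
  up <- update_q(q, "left", 0.5, q_alpha = 0.3)
  expect_equal(up$rpe, 0)
  expect_equal(up$q, q)
  # full learning rate copies the reward
  expect_equal(update_q(q, "right", 0.8, q_alpha = 1)$q[["right"]], 0.8)
  # q_alpha 0.1, Q 0.5, reward 1 -> Q 0.55, RPE 0.5
  up <- update_q(q, "left", 1, q_alpha = 0.1)
  expect_equal(up$q[["left"]], 0.55)
  expect_equal(up$rpe, 0.5)
  expect_equal(up$q[["right"]], 0.5)  # other actions unchanged
  expect_error(update_q(q, "middle", 1), "unknown action")
})

test_that("Q stays within [0,1] for rewards and initial values in [0,1]", {
  set.seed(8)
  q <- c(a = 0.5, b = 0.5)
  for (i in 1:500) {
    q <- update_q(q, sample(c("a", "b"), 1), runif(1), q_alpha = 0.4)$q
    expect_true(all(q >= 0 & q <= 1))
  }
})

test_that("phasic dopamine decays exponentially from C_scale * RPE", {
  t <- seq(0, 100, by = 1)
  expect_equal(dopamine_signal(0, 30, 20, t), rep(0, length(t)))
  tr <- dopamine_signal(0.5, 30, 20, t)
  expect_equal(tr[1], 15)
  # amplitude halves every tau ln 2
  half <- 20 * log(2)
  expect_equal(dopamine_signal(0.5, 30, 20, half) /
                 dopamine_signal(0.5, 30, 20, 0), 0.5, tolerance = 1e-12)
  # sign of the trace matches the sign of the RPE throughout
  expect_true(all(dopamine_signal(-0.4, 30, 20, t) < 0))
  expect_true(all(tr > 0))
})

test_that("weight updates push dSPN up and iSPN down for positive dopamine", {
  w <- data.frame(channel = rep(c("left", "right"), each = 2),
                  target = rep(c("dSPN", "iSPN"), 2),
                  w = 0.01, stringsAsFactors = FALSE)
  dp <- list(dpmn_alphaw = 39.5, dpmn_wmax = 0.08)
  ip <- list(dpmn_alphaw = -38.2, dpmn_wmax = 0.06)
  elig <- list(dSPN = 4e-4, iSPN = 4e-4)

  up <- update_weights(w, "left", dopamine = 0.15, elig, dp, ip)
  expect_gt(up$w[up$channel == "left" & up$target == "dSPN"], 0.01)
  expect_lt(up$w[up$channel == "left" & up$target == "iSPN"], 0.01)
  # unselected channel untouched
  expect_equal(up$w[up$channel == "right"], c(0.01, 0.01))
  # opposite signs for a dopamine dip
  dn <- update_weights(w, "left", dopamine = -0.15, elig, dp, ip)
  expect_lt(dn$w[dn$channel == "left" & dn$target == "dSPN"], 0.01)
  expect_gt(dn$w[dn$channel == "left" & dn$target == "iSPN"], 0.01)
  # dopamine at baseline: no change; plasticity disabled: identity
  expect_equal(update_weights(w, "left", 0, elig, dp, ip), w)
  expect_equal(update_weights(w, "left", 5, elig, dp, ip, enabled = FALSE), w)
})

test_that("weights saturate at dpmn_wmax and never leave [0, wmax]", {
  w <- data.frame(channel = "left", target = c("dSPN", "iSPN"), w = 0.01,
                  stringsAsFactors = FALSE)
  dp <- list(dpmn_alphaw = 39.5, dpmn_wmax = 0.08)
  ip <- list(dpmn_alphaw = -38.2, dpmn_wmax = 0.06)
  elig <- list(dSPN = 4e-4, iSPN = 4e-4)
  for (i in 1:200) {
    w <- update_weights(w, "left", 0.5, elig, dp, ip)
    expect_true(all(w$w >= 0 & w$w <= 0.08))
  }
  expect_equal(w$w[w$target == "dSPN"], 0.08)  # clipped at the ceiling
  expect_equal(w$w[w$target == "iSPN"], 0)     # floored at zero
  for (i in 1:200) w <- update_weights(w, "left", -0.5, elig, dp, ip)
  expect_equal(w$w[w$target == "dSPN"], 0)
  expect_equal(w$w[w$target == "iSPN"], 0.06)
})

test_that("choice statistics depend on weights, not on Q values", {
  # with plasticity off, runs differing only in Q initialization are identical
  fx1 <- tiny_cfg(seed = 31, n_trials = 3, Q_df = data.frame(left = 0.9,
                                                             right = 0.1))
  fx2 <- tiny_cfg(seed = 31, n_trials = 3, Q_df = data.frame(left = 0.1,
                                                             right = 0.9))
  r1 <- run_tiny(fx1)[[1]]
  r2 <- run_tiny(fx2)[[1]]
  expect_identical(r1$datatables$decision, r2$datatables$decision)
  expect_identical(r1$datatables$decision_time, r2$datatables$decision_time)
})

test_that("disabled plasticity leaves weights and Q untouched end-to-end", {
  fx <- tiny_cfg(seed = 41, n_trials = 3,
                 record_variables = c("weight"))
  r <- run_tiny(fx)[[1]]
  expect_true(all(r$recordings$weight$w ==
                    fx$paramfile$dSPNdefaults$dpmn_w0))
  expect_true(all(r$Q_df$left == 0.5 & r$Q_df$right == 0.5))
})
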