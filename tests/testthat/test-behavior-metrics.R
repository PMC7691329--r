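make_trials <- function(cue, outcome, laser = FALSE, rt = 0.4) {
  tibble::tibble(
    cue_side = cue, laser = laser, outcome = outcome,
    response_time_s = ifelse(outcome == "correct", rt, NA_real_)
  )
}

test_that("performance summary uses the right denominators", {
  # 10 right-cue trials: 6 correct, 2 incorrect, 2 timeout
  tr <- make_trials(rep("right", 10),
                    c(rep("correct", 6), rep("incorrect", 2),
                      rep("timeout", 2)))
  perf <- performance_summary(tr, "inward", "left")
  expect_equal(perf$timeout_rate, 0.2)
  expect_equal(perf$incorrect_rate, 0.25)
  expect_equal(perf$correct_rate, 0.75)
  expect_equal(perf$cue_class, "contraversive")
  # all-timeout cell: incorrect undefined, flagged
  to <- performance_summary(make_trials(rep("left", 4), rep("timeout", 4)),
                            "inward", "left")
  expect_false(to$rates_defined)
  expect_true(is.na(to$incorrect_rate))
  expect_equal(to$timeout_rate, 1)
})

test_that("side preference matches its defining ratio", {
  tr <- dplyr::bind_rows(
    make_trials(rep("right", 8), c(rep("correct", 6), rep("incorrect", 2))),
    make_trials(rep("left", 8), c(rep("correct", 2), rep("incorrect", 6)))
  )
  perf <- performance_summary(tr, "inward", "left")
  # contra (right cue) 0.75 vs ipsi (left cue) 0.25 -> 0.5
  expect_equal(side_preference(perf), 0.5)
  # symmetric performance -> 0
  sym <- dplyr::bind_rows(
    make_trials(rep("right", 4), c("correct", "correct", "incorrect",
                                   "incorrect")),
    make_trials(rep("left", 4), c("correct", "correct", "incorrect",
                                  "incorrect"))
  )
  expect_equal(side_preference(performance_summary(sym, "inward", "left")), 0)
})

test_that("laser bias index reproduces hand-computed values", {
  # nl pair 0.8 + 0.2 = 1.0, laser pair 0.9 + 0.3 = 1.2 -> 0.2
  tr <- dplyr::bind_rows(
    make_trials(rep("right", 100),
                rep(c("correct", "incorrect"), c(80, 20))),
    make_trials(rep("left", 100),
                rep(c("correct", "incorrect"), c(80, 20))),
    make_trials(rep("right", 100),
                rep(c("correct", "incorrect"), c(90, 10)), laser = TRUE),
    make_trials(rep("left", 100),
                rep(c("correct", "incorrect"), c(70, 30)), laser = TRUE)
  )
  perf <- performance_summary(tr, "inward", "left")
  expect_equal(laser_delta_index(perf, "contra_action"), 0.2,
               tolerance = 1e-12)
  expect_equal(laser_delta_index(perf, "right_stimulus"), 0.2,
               tolerance = 1e-12)
  # equal laser and non-laser rates -> 0
  eq <- dplyr::bind_rows(
    make_trials(rep(c("right", "left"), each = 10),
                rep(c("correct", "incorrect"), 10)),
    make_trials(rep(c("right", "left"), each = 10),
                rep(c("correct", "incorrect"), 10), laser = TRUE)
  )
  expect_equal(laser_delta_index(performance_summary(eq, "inward", "left")),
               0)
})

test_that("laser bias index is label-consistent across contingencies", {
  # identical trial table read as outward: cue_class flips, so the
  # contra-action pair is built from the other cells but the formula is
  # unchanged
  tr <- dplyr::bind_rows(
    make_trials(rep("right", 50), rep(c("correct", "incorrect"), c(40, 10))),
    make_trials(rep("left", 50), rep(c("correct", "incorrect"), c(35, 15))),
    make_trials(rep("right", 50), rep(c("correct", "incorrect"), c(45, 5)),
                laser = TRUE),
    make_trials(rep("left", 50), rep(c("correct", "incorrect"), c(25, 25)),
                laser = TRUE)
  )
  inw <- performance_summary(tr, "inward", "left")
  outw <- performance_summary(tr, "outward", "left")
  d_in <- laser_delta_index(inw, "contra_action")
  # inward: pair = right_corr + left_incorr; outward: left_corr + right_incorr
  expect_equal(d_in, ((45 / 50 + 25 / 50) - (40 / 50 + 15 / 50)) /
                 (40 / 50 + 15 / 50))
  d_out <- laser_delta_index(outw, "contra_action")
  expect_equal(d_out, ((25 / 50 + 5 / 50) - (35 / 50 + 10 / 50)) /
                 (35 / 50 + 10 / 50))
  # right-stimulus mode ignores the contingency entirely
  expect_equal(laser_delta_index(inw, "right_stimulus"),
               laser_delta_index(outw, "right_stimulus"))
})

test_that("spontaneous deltas follow their defining ratios", {
  rates <- tibble::tibble(
    laser = c(FALSE, TRUE), n_attempts = c(100, 50),
    contraversive = c(0.6, 0.3), ipsiversive = c(0.4, 0.7)
  )
  d <- spontaneous_delta(rates)
  expect_equal(d$delta_contraversive, -0.5)
  expect_equal(d$delta_ipsiversive, 0.75)
  # equal proportions -> zero deltas
  eq <- tibble::tibble(laser = c(FALSE, TRUE), n_attempts = c(10, 10),
                       contraversive = c(0.5, 0.5),
                       ipsiversive = c(0.5, 0.5))
  expect_equal(unlist(spontaneous_delta(eq)), c(delta_contraversive = 0,
                                                delta_ipsiversive = 0))
  zero <- tibble::tibble(laser = c(FALSE, TRUE), n_attempts = c(5, 5),
                         contraversive = c(0, 1), ipsiversive = c(1, 0))
  expect_error(spontaneous_delta(zero), "zero")
})

test_that("movement velocity averages instantaneous speed from start to threshold", {
  # pure ramp: 15 degrees over 0.5 s -> 30 deg/s
  t <- seq(0.01, 0.6, 0.01)
  ramp <- make_trace(t, t * 30)
  expect_equal(movement_velocity(ramp, 15), 30, tolerance = 1e-9)
  # sub-criterion trace flagged as NA
  expect_true(is.na(movement_velocity(make_trace(t, rep(0.2, 60)), 15)))
  # piecewise ramp with a pause: hand-computed mean of |steps|
  t6 <- seq(0.01, 0.06, 0.01)
  a6 <- c(0.2, 0.8, 0.8, 5, 10, 16)
  # movement start at sample 2 (0.8 > 0.5), threshold at sample 6
  steps <- abs(diff(a6[2:6])) / 0.01
  expect_equal(movement_velocity(make_trace(t6, a6), 15), mean(steps))
})

test_that("cohort laser-effect analysis recovers injected effects and is mouse-order invariant", {
  ag <- agent_params(laser_delta_contra = 0.15, p_timeout = 0.08)
  cfg <- task_config(laser_fraction = 0.3)
  coh <- simulate_behavior_cohort(ag, cfg, n_mice = 5, n_sessions = 1,
                                  trials_per_session = 600, seed = 42,
                                  traces = FALSE)
  res <- laser_effect_analysis(coh, n_perm = 300, seed = 7)
  s <- res$summary
  expect_true(s$significant[s$metric == "contra_action"])
  expect_gt(s$observed[s$metric == "contra_action"], 0.1)
  # laser raises incorrect on left (ipsi-cued) trials for a positive
  # contra shift
  expect_gt(s$observed[s$metric == "incorrect_left"], 0)
  # permuting mouse order leaves every output unchanged
  res2 <- laser_effect_analysis(rev(coh$sessions), n_perm = 300, seed = 7)
  expect_equal(res$summary$observed, res2$summary$observed)
  expect_equal(res$summary$p, res2$summary$p)
})

test_that("hemisphere relabeling flips the side-preference sign", {
  tr <- dplyr::bind_rows(
    make_trials(rep("right", 10), rep(c("correct", "incorrect"), c(9, 1))),
    make_trials(rep("left", 10), rep(c("correct", "incorrect"), c(5, 5)))
  )
  pl <- side_preference(performance_summary(tr, "inward", "left"))
  pr <- side_preference(performance_summary(tr, "inward", "right"))
  expect_equal(pl, -pr)
})
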