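test_that("trial classification follows the cumulative-angle rule", {
  cfg <- task_config()
  ramp <- make_trace(seq(0.01, 1, 0.01), seq(0.01, 1, 0.01) / 0.4 * 15)
  res <- classify_trial(ramp, "right", cfg)
  expect_equal(res$outcome, "correct")
  expect_equal(res$response_time_s, 0.4)
  expect_equal(res$chosen_direction, "pos")
  # same trace, left cue: the positive crossing is now incorrect
  expect_equal(classify_trial(ramp, "left", cfg)$outcome, "incorrect")
  # flat trace times out
  flat <- make_trace(seq(0.01, 1, 0.01), rep(0, 100))
  expect_equal(classify_trial(flat, "right", cfg)$outcome, "timeout")
  expect_true(is.na(classify_trial(flat, "right", cfg)$response_time_s))
  # wrong-direction excursion must be offset: -5 deg then net +15 at 0.8 s
  t <- seq(0.01, 1, 0.01)
  ang <- c(seq(-0.25, -5, length.out = 20),
           seq(-5, 15, length.out = 60)[-1], rep(15.5, 21))
  exc <- make_trace(t, ang)
  # cumulative-sum oracle on the sample sequence
  first_cross <- t[which(abs(ang) >= 15)[1]]
  res2 <- classify_trial(exc, "right", cfg)
  expect_equal(res2$outcome, "correct")
  expect_equal(res2$response_time_s, first_cross)
  expect_error(classify_trial(make_trace(c(0.2, 0.1), c(1, 2)), "right", cfg),
               "increasing")
})

test_that("classification ignores samples after the first crossing", {
  cfg <- task_config()
  t <- seq(0.01, 1, 0.01)
  ang <- pmin(t / 0.3, 1) * 15
  base <- classify_trial(make_trace(t, ang), "right", cfg)
  extended <- classify_trial(
    make_trace(c(t, t[length(t)] + t), c(ang, -ang)), "right", cfg)
  expect_equal(base$outcome, extended$outcome)
  expect_equal(base$response_time_s, extended$response_time_s)
})

test_that("inward/outward duality swaps correct and incorrect only", {
  withr::with_seed(19, {
    for (i in 1:300) {
      tr <- random_trace()
      cue <- sample(c("left", "right"), 1)
      a <- classify_trial(tr, cue, task_config("inward"))
      b <- classify_trial(tr, cue, task_config("outward"))
      expect_equal(a$response_time_s, b$response_time_s)
      expect_equal(a$chosen_direction, b$chosen_direction)
      if (a$outcome == "timeout") {
        expect_equal(b$outcome, "timeout")
      } else {
        expect_equal(b$outcome,
                     setdiff(c("correct", "incorrect"), a$outcome))
      }
    }
  })
})

test_that("anti-bias repeats the cue until answered correctly", {
  expect_equal(anti_bias_next_cue("right", "incorrect"), "right")
  expect_equal(anti_bias_next_cue("left", "timeout"), "left")
  withr::with_seed(2, {
    draws <- replicate(4000, anti_bias_next_cue("right", "correct"))
  })
  expect_gt(mean(draws == "right"), 0.45)
  expect_lt(mean(draws == "right"), 0.55)
})

test_that("laser schedules hit the target fraction with no adjacent pairs", {
  expect_identical(laser_schedule(50, 0), rep(FALSE, 50))
  withr::with_seed(13, {
    for (i in 1:50) {
      n <- sample(100:400, 1)
      f <- runif(1, 0.05, 0.45)
      s <- laser_schedule(n, f)
      expect_false(any(s[-1] & s[-n]))
      expect_lt(abs(mean(s) - f), 0.02 + 1 / n)
    }
  })
  expect_error(laser_schedule(100, 0.6), "0.5")
})

test_that("closed-loop sessions classify agents as expected and reproduce", {
  cfg <- task_config(laser_fraction = 0.3)
  ses <- run_session(correct_agent(cfg), cfg, 60, seed = 4)
  expect_equal(unique(ses$trials$outcome), "correct")
  still <- run_session(still_agent(cfg), cfg, 30, seed = 4)
  expect_equal(unique(still$trials$outcome), "timeout")
  # bit-reproducibility
  a <- run_session(make_task_agent(agent_params(), cfg), cfg, 50, seed = 77)
  b <- run_session(make_task_agent(agent_params(), cfg), cfg, 50, seed = 77)
  expect_identical(a$trials$outcome, b$trials$outcome)
  expect_identical(a$trials$response_time_s, b$trials$response_time_s)
  # stochastic agent with p(correct) = 0.8 lands near a 20% error rate
  ag <- agent_params(p_correct_right = 0.8, p_correct_left = 0.8,
                     p_timeout = 0)
  ses2 <- run_session(make_task_agent(ag, cfg), cfg, 1000, seed = 5)
  inc <- mean(ses2$trials$outcome == "incorrect")
  ci <- binomial_ci(200, 1000)
  expect_gt(inc, ci$lo - 0.02)
  expect_lt(inc, ci$hi + 0.02)
})

test_that("spontaneous sessions apply both anti-bias rules", {
  cfg <- task_config()
  ses <- spontaneous_session(correct_agent(cfg, rt = 0.5), cfg, 40, seed = 3)
  tr <- ses$trials
  # agent always moves +: rewarded iff designated is pos, and the
  # designation switches after every reward, repeats otherwise
  for (i in seq_len(nrow(tr) - 1)) {
    if (tr$rewarded[i]) {
      expect_false(tr$designated_direction[i + 1] ==
                     tr$designated_direction[i])
    } else {
      expect_equal(tr$designated_direction[i + 1],
                   tr$designated_direction[i])
    }
    expect_equal(tr$rewarded[i],
                 tr$movement_direction[i] == tr$designated_direction[i])
  }
  # non-moving agent attempts nothing
  none <- spontaneous_session(still_agent(cfg), cfg, 20, seed = 3)
  expect_true(all(is.na(none$trials$movement_direction)))
  expect_false(any(none$trials$rewarded))
})

test_that("hemisphere relabeling swaps action labels but not outcomes", {
  cfg <- task_config(laser_fraction = 0.2)
  ag <- agent_params(p_timeout = 0.05)
  left <- run_session(make_task_agent(ag, cfg, "left"), cfg, 200, seed = 21,
                      hemisphere = "left")
  perf_l <- performance_summary(left)
  perf_r <- performance_summary(left$trials, cfg$contingency, "right")
  # outcomes and rates identical; only the cue_class labels swap
  expect_equal(perf_l$incorrect_rate, perf_r$incorrect_rate)
  expect_equal(perf_l$timeout_rate, perf_r$timeout_rate)
  expect_true(all(perf_l$cue_class != perf_r$cue_class))
})
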