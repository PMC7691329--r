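make_dff_obj <- function(mat, frame_rate = 5) {
  structure(
    list(dff = mat, f0 = rep(100, nrow(mat)),
         valid = rep(TRUE, nrow(mat)),
         frame_times = (seq_len(ncol(mat)) - 1) / frame_rate,
         frame_rate_hz = frame_rate,
         roi_labels = rep("unlabeled", nrow(mat)),
         neuropil_coefficient = 0.7, detrended = FALSE, zscored = FALSE),
    class = "dff_traces"
  )
}

test_that("neuropil correction and density-mode F0 behave on constructed traces", {
  n_f <- 600
  ft <- (seq_len(n_f) - 1) / 5
  # constant soma, zero neuropil: F0 = c, DFF = 0
  ts <- roi_trace_set(matrix(80, 1, n_f), matrix(0, 1, n_f), ft)
  d <- neuropil_dff(ts)
  expect_equal(d$f0, 80)
  expect_true(all(abs(d$dff) < 1e-9))
  # soma = 0.7 x neuropil: corrected trace is 0, roi flagged invalid
  np <- matrix(100 + rnorm(n_f, 0, 1), 1, n_f)
  ts2 <- roi_trace_set(0.7 * np, np, ft)
  d2 <- neuropil_dff(ts2)
  expect_false(d2$valid[1])
  # two-level trace: 80% of time at 100, 20% at 200 -> F0 ~ 100,
  # peak DFF ~ 100%
  lev <- c(rep(100, 480), rep(200, 120)) + rnorm(n_f, 0, 0.5)
  ts3 <- roi_trace_set(matrix(lev, 1), matrix(0, 1, n_f), ft)
  d3 <- neuropil_dff(ts3)
  expect_lt(abs(d3$f0 - 100), 2)
  expect_lt(abs(max(d3$dff) - 100), 5)
  # bouton rois skip the subtraction
  tsb <- roi_trace_set(matrix(lev, 1), NULL, ft,
                       roi_labels = "bouton")
  expect_lt(abs(neuropil_dff(tsb)$f0 - 100), 2)
})

test_that("detrending removes slow drift, preserves transients, and is idempotent", {
  n_f <- 3000  # 10 min at 5 Hz
  t <- (seq_len(n_f) - 1) / 5
  withr::with_seed(8, {
    transients <- numeric(n_f)
    # transients spaced so the trace returns to baseline between events,
    # the operating assumption of the min/max envelope method
    onset_times <- 5 + cumsum(runif(38, 12, 18))
    onsets <- round(onset_times[onset_times < 580] * 5)
    k <- exp(-(0:40) / 7.5)
    for (o in onsets) {
      idx <- o:min(n_f, o + 40)
      transients[idx] <- transients[idx] + 30 * k[seq_along(idx)]
    }
  })
  drift <- 20 * t / 600  # 20% DFF per 10 min
  obj <- make_dff_obj(rbind(transients + drift, rep(3, n_f)))
  det <- detrend_baseline(obj)
  # constant trace maps to zero
  expect_lt(max(abs(det$dff[2, ])), 1e-9)
  # drift removed on quiet frames
  quiet <- transients < 0.5
  expect_lt(abs(median(det$dff[1, quiet])), 2)
  # transient peaks preserved within 5%
  nodrift <- detrend_baseline(make_dff_obj(rbind(transients, rep(0, n_f))))
  for (o in onsets[1:10]) {
    expect_lt(abs(det$dff[1, o] - transients[o]) / 30, 0.05)
    expect_lt(abs(nodrift$dff[1, o] - transients[o]) / 30, 0.05)
  }
  # idempotent within 1% RMS
  twice <- detrend_baseline(det)
  rel <- sqrt(mean((twice$dff[1, ] - det$dff[1, ])^2)) /
    sqrt(mean(det$dff[1, ]^2))
  expect_lt(rel, 0.01)
  expect_error(detrend_baseline(make_dff_obj(matrix(0, 1, 100))),
               "shorter")
})

test_that("z-scoring standardizes each valid roi", {
  withr::with_seed(4, {
    obj <- make_dff_obj(matrix(rnorm(5 * 400, 10, 3), 5))
  })
  z <- zscore_dff(obj)
  expect_true(all(abs(rowMeans(z$dff)) < 1e-10))
  expect_true(all(abs(apply(z$dff, 1, sd) - 1) < 1e-10))
})

test_that("trial tensors align, label, and apply the inclusion rule", {
  cfg <- task_config(laser_fraction = 0)
  ag <- agent_params(p_correct_right = 0.7, p_correct_left = 0.7,
                     p_timeout = 0.05)
  ses <- run_session(make_task_agent(ag, cfg), cfg, 80, seed = 14)
  sim <- simulate_calcium_session(ses, calcium_sim_params(n_neurons = 8),
                                  seed = 15)
  z <- zscore_dff(detrend_baseline(neuropil_dff(sim$traces)))
  tens <- build_trial_tensor(z, ses, anchor = "stimulus")
  # condition counts match generator tallies
  tr <- ses$trials[ses$trials$outcome != "timeout", ]
  act <- ifelse((tr$chosen_direction == "pos"), "contra", "ipsi")
  expect_equal(as.integer(tens$condition_counts["right-contra"]),
               sum(tr$cue_side == "right" & act == "contra"))
  expect_equal(sum(tens$condition_counts), nrow(tr))
  expect_equal(dim(tens$activity)[2], nrow(tr))
  # a session with a sparse condition is excluded
  few <- ses
  drop_idx <- which(few$trials$cue_side == "right" &
                      few$trials$chosen_direction == "neg")
  keep <- setdiff(seq_len(nrow(few$trials)), drop_idx[-(1:4)])
  few$trials <- few$trials[keep, ]
  tens_few <- build_trial_tensor(z, few, anchor = "stimulus")
  expect_false(tens_few$included)
  # shifting every onset by one frame shifts the content by one frame
  shifted <- ses
  shifted$trials$onset_time_s <- shifted$trials$onset_time_s + 0.2
  tens_sh <- build_trial_tensor(z, shifted, anchor = "stimulus")
  expect_equal(tens$activity[, , 2:dim(tens$activity)[3]],
               tens_sh$activity[, , 1:(dim(tens_sh$activity)[3] - 1)])
})

test_that("condition statistics recover injected action tuning", {
  cfg <- task_config(laser_fraction = 0)
  ag <- agent_params(p_correct_right = 0.75, p_correct_left = 0.75,
                     p_timeout = 0.05)
  ses <- run_session(make_task_agent(ag, cfg), cfg, 150, seed = 23)
  params <- calcium_sim_params(n_neurons = 40, action_ipsi_bias = 0.6,
                               cue_weight_sd = 0.1)
  sim <- simulate_calcium_session(ses, params, seed = 24)
  z <- zscore_dff(detrend_baseline(neuropil_dff(sim$traces)))
  tens <- build_trial_tensor(z, ses, anchor = "stimulus")
  st <- neuron_condition_stats(tens)
  # ipsi-weighted tuning: population responds more on ipsiversive trials
  expect_gt(mean(st$per_neuron$ipsi - st$per_neuron$contra, na.rm = TRUE), 0)
  con <- st$contrasts
  expect_lt(con$z[con$contrast == "contra_vs_ipsi_action"], 0) # ipsi > contra
  # marginals are the average of their two condition means
  pn <- st$per_neuron
  expect_equal(pn$right_cue, (pn$right_contra + pn$right_ipsi) / 2)
  expect_equal(pn$contra, (pn$right_contra + pn$left_contra) / 2)
  # fraction-significant table carries exact binomial CIs
  fs <- st$fraction_significant
  expect_true(all(fs$lo <= fs$fraction & fs$fraction <= fs$hi,
                  na.rm = TRUE))
})

test_that("velocity median split compares high and low velocity trials", {
  cfg <- task_config(laser_fraction = 0)
  ses <- run_session(make_task_agent(agent_params(p_timeout = 0), cfg),
                     cfg, 60, seed = 31)
  sim <- simulate_calcium_session(ses, calcium_sim_params(n_neurons = 6),
                                  seed = 32)
  z <- zscore_dff(detrend_baseline(neuropil_dff(sim$traces)))
  tens <- build_trial_tensor(z, ses, anchor = "stimulus")
  vel <- vapply(tens$trials$trial, function(i) {
    movement_velocity(ses$trials$trace[[i]], cfg$threshold_deg)
  }, numeric(1))
  st <- neuron_condition_stats(tens, velocities = vel)
  expect_false(is.null(st$velocity_split))
  expect_equal(st$velocity_split$n_high + st$velocity_split$n_low,
               sum(!is.na(vel)))
})

test_that("bouton statistics saturate for perfectly selective boutons", {
  sim <- simulate_bouton_passive(n_boutons = 12, contra_frac = 1,
                                 effect_size = 2, n_trials_per_side = 15,
                                 params = calcium_sim_params(noise_sd = 0.01),
                                 seed = 41)
  dff <- neuropil_dff(sim$traces)
  bs <- bouton_visual_stats(dff, sim$stim_table, n_shuffles = 300, seed = 42)
  pb <- bs$per_bouton
  expect_true(all(pb$responsive))
  expect_true(all(pb$preference_score > 0.9))
  expect_true(all(pb$preference_significant))
  expect_equal(bs$population$n_contra_preferring, 12)
  # preference score bounded and equal to 2*(auroc - 0.5)
  expect_true(all(abs(pb$preference_score) <= 1))
  expect_equal(pb$preference_score, 2 * (pb$auroc - 0.5))
})

test_that("population comparison reproduces the extreme printed contrast", {
  res <- compare_preference_populations(233, 268, 48, 309)
  expect_lt(res$log10_p, -70)
  expect_gt(res$log10_p, -73)
  expect_equal(res$prop_a, 233 / 268, tolerance = 1e-12)
})
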