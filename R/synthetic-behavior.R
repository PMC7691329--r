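#' Ground-truth parameters for a simulated task agent
#'
#' Describes a stochastic agent for the trackball task. On each trial the
#' agent times out with probability `p_timeout`; otherwise it selects a
#' rotation direction. The probability of answering a cue correctly is
#' `p_correct_right` / `p_correct_left`; on laser trials
#' `laser_delta_contra` is added to the probability of choosing the
#' contraversive direction (clipped to \[0, 1\]; clips are counted in the
#' cohort ground truth). Response times are log-normal, truncated to the
#' response window; defaults target a ~0.4 s median, in the range reported
#' for expert mice (roughly 0.26-0.57 s).
#'
#' @param p_correct_right,p_correct_left Per-cue probability of a correct
#'   choice on completed non-laser trials.
#' @param laser_delta_contra Additive laser-trial change in the probability
#'   of the contraversive action.
#' @param p_timeout Probability of no threshold crossing in the window.
#' @param rt_meanlog,rt_sdlog Log-normal response-time parameters.
#' @param velocity_scale Typical ball speed (deg/s) used when synthesizing
#'   sub-threshold wander on timeout trials.
#' @return An `agent_params` list.
#' @export
agent_params <- function(p_correct_right = 0.8,
                         p_correct_left = 0.8,
                         laser_delta_contra = 0,
                         p_timeout = 0.1,
                         rt_meanlog = log(0.4),
                         rt_sdlog = 0.35,
                         velocity_scale = 30) {
  stopifnot(p_correct_right >= 0, p_correct_right <= 1,
            p_correct_left >= 0, p_correct_left <= 1,
            p_timeout >= 0, p_timeout < 1,
            rt_sdlog > 0, velocity_scale > 0)
  structure(
    list(
      p_correct_right = p_correct_right,
      p_correct_left = p_correct_left,
      laser_delta_contra = laser_delta_contra,
      p_timeout = p_timeout,
      rt_meanlog = rt_meanlog,
      rt_sdlog = rt_sdlog,
      velocity_scale = velocity_scale
    ),
    class = "agent_params"
  )
}

# Probability that the agent chooses the positive rotation, given cue,
# laser flag, hemisphere and contingency. Returns the (possibly clipped)
# probability with a "clipped" attribute counting clip events.
prob_positive_choice <- function(cue_side, laser, agent, contingency,
                                 hemisphere) {
  p_correct <- if_else(cue_side == "right",
                       agent$p_correct_right, agent$p_correct_left)
  pos_is_correct <- correct_direction(cue_side, contingency) == "pos"
  p_pos <- if_else(pos_is_correct, p_correct, 1 - p_correct)
  contra_is_pos <- hemisphere == "left"
  p_contra <- if (contra_is_pos) p_pos else 1 - p_pos
  p_contra_l <- p_contra + agent$laser_delta_contra
  clipped <- laser & (p_contra_l < 0 | p_contra_l > 1)
  p_contra <- if_else(laser, pmin(1, pmax(0, p_contra_l)), p_contra)
  p_pos <- if (contra_is_pos) p_contra else 1 - p_contra
  attr(p_pos, "clipped") <- sum(clipped)
  p_pos
}

# Truncated log-normal response times within (lo, hi).
draw_rts <- function(n, agent, lo, hi) {
  rt <- rlnorm(n, agent$rt_meanlog, agent$rt_sdlog)
  pmin(pmax(rt, lo), hi)
}

# Ramp trace reaching sign*threshold at rt, sampled at the ball tick, with
# mild sub-degree noise; continues briefly past the crossing.
synth_response_trace <- function(direction, rt, config, noise_sd = 0.3) {
  thr <- config$threshold_deg
  sgn <- if (direction == "pos") 1 else -1
  t_end <- min(rt + 0.1, config$response_window_s + 0.1)
  t <- seq(config$tick_s, t_end, by = config$tick_s)
  base <- sgn * thr * pmin(t / rt, 1.05)
  wig <- rnorm(length(t), 0, noise_sd)
  # keep noise from triggering an early or opposite crossing
  ang <- base + wig * pmin(1, abs(thr - abs(base)) / (4 * noise_sd + 1e-9))
  ang[t >= rt] <- pmax(abs(base[t >= rt]), thr) * sgn
  tibble(time_s = t, angle_deg = ang)
}

# Sub-threshold wander for timeout / no-move trials.
synth_timeout_trace <- function(config, velocity_scale, thr_frac = 0.6) {
  t <- seq(config$tick_s, config$response_window_s, by = config$tick_s)
  w <- cumsum(rnorm(length(t), 0, velocity_scale * config$tick_s / 3))
  cap <- thr_frac * config$threshold_deg
  peak <- max(abs(w), 1e-9)
  if (peak > cap) {
    w <- w * cap / peak
  }
  tibble(time_s = t, angle_deg = w)
}

#' Build a stochastic task agent policy
#'
#' Returns a `(cue_side, laser) -> trace` closure implementing the
#' generative model of [agent_params()], suitable for [run_session()]. With
#' `cue_side = NA` (spontaneous sessions) the agent attempts a movement
#' with probability `1 - p_timeout` and chooses the contraversive direction
#' with probability 0.5 plus the laser shift.
#'
#' @param agent An [agent_params()].
#' @param config A [task_config()].
#' @param hemisphere Analysis hemisphere the laser shift is defined
#'   against.
#' @export
make_task_agent <- function(agent, config, hemisphere = "left") {
  force(agent); force(config); force(hemisphere)
  function(cue_side, laser) {
    if (is.na(cue_side)) {
      if (runif(1) < agent$p_timeout) {
        return(synth_timeout_trace(config, agent$velocity_scale))
      }
      p_contra <- min(1, max(0, 0.5 + if (laser) agent$laser_delta_contra else 0))
      contra_dir <- if (hemisphere == "left") "pos" else "neg"
      dir <- if (runif(1) < p_contra) contra_dir else setdiff(c("pos", "neg"), contra_dir)
      rt <- draw_rts(1, agent, 2 * config$tick_s,
                     config$spontaneous_trial_s - config$tick_s)
      cfg5 <- config
      cfg5$threshold_deg <- config$spontaneous_threshold_deg
      cfg5$response_window_s <- config$spontaneous_trial_s
      return(synth_response_trace(dir, rt, cfg5))
    }
    if (runif(1) < agent$p_timeout) {
      return(synth_timeout_trace(config, agent$velocity_scale))
    }
    p_pos <- prob_positive_choice(cue_side, laser, agent,
                                  config$contingency, hemisphere)
    dir <- if (runif(1) < p_pos) "pos" else "neg"
    rt <- draw_rts(1, agent, 2 * config$tick_s,
                   config$response_window_s - config$tick_s)
    synth_response_trace(dir, rt, config)
  }
}

# Vectorized outcome-level trial draw (no traces); same generative model as
# make_task_agent + classify_trial, used for large calibration runs.
draw_trial_outcomes <- function(n_trials, agent, config, hemisphere) {
  cue <- sample(c("left", "right"), n_trials, replace = TRUE)
  laser <- laser_schedule(n_trials, config$laser_fraction)
  timeout <- runif(n_trials) < agent$p_timeout
  p_pos <- prob_positive_choice(cue, laser, agent, config$contingency,
                                hemisphere)
  dir <- if_else(runif(n_trials) < p_pos, "pos", "neg")
  dir[timeout] <- NA_character_
  correct <- dir == correct_direction(cue, config$contingency)
  outcome <- dplyr::case_when(
    timeout ~ "timeout",
    correct ~ "correct",
    .default = "incorrect"
  )
  rt <- draw_rts(n_trials, agent, 2 * config$tick_s,
                 config$response_window_s - config$tick_s)
  rt[timeout] <- NA_real_
  tibble(
    trial = seq_len(n_trials),
    onset_time_s = (seq_len(n_trials) - 1) *
      (config$hold_still_s + config$response_window_s + config$iti_s),
    cue_side = cue,
    laser = laser,
    outcome = outcome,
    response_time_s = rt,
    chosen_direction = dir,
    n_clipped = attr(p_pos, "clipped")
  )
}

#' Simulate a cohort of optogenetic behavior sessions
#'
#' Generates per-mouse session logs from the [agent_params()] generative
#' model under a shared [task_config()], together with a ground-truth
#' record (true per-cue probabilities, laser shift, and the analytic
#' contraversive-action-bias change implied by them) for parameter-recovery
#' tests.
#'
#' @param agent An [agent_params()]; shared by all mice.
#' @param task A [task_config()]; set `laser_fraction > 0` for laser
#'   sessions.
#' @param n_mice,n_sessions,trials_per_session Cohort dimensions (defaults
#'   6 mice, 3 sessions, 300 trials).
#' @param seed Optional integer seed.
#' @param hemisphere Hemisphere the laser shift is defined against.
#' @param traces Synthesize full ball traces (`TRUE`, default) or draw
#'   outcome-level trials only (`FALSE`; much faster, no velocity data).
#' @return A `behavior_cohort`: `sessions` (list of `session_log`),
#'   `ground_truth` (one-row tibble), `agent`, `task`.
#' @export
simulate_behavior_cohort <- function(agent = agent_params(),
                                     task = task_config(laser_fraction = 0.3),
                                     n_mice = 6, n_sessions = 3,
                                     trials_per_session = 300,
                                     seed = NULL, hemisphere = "left",
                                     traces = TRUE) {
  stopifnot(n_mice >= 1, n_sessions >= 1, trials_per_session >= 1)
  sessions <- list()
  k <- 0
  for (m in seq_len(n_mice)) {
    for (s in seq_len(n_sessions)) {
      k <- k + 1
      s_seed <- child_seed(seed, k)
      log <- if (traces) {
        run_session(make_task_agent(agent, task, hemisphere), task,
                    trials_per_session, seed = s_seed,
                    mouse_id = sprintf("m%02d", m), hemisphere = hemisphere)
      } else {
        trials <- with_seed(s_seed,
                            draw_trial_outcomes(trials_per_session, agent,
                                                task, hemisphere))
        new_session_log(sprintf("m%02d", m), hemisphere, task$contingency,
                        trials, task, s_seed)
      }
      sessions[[k]] <- log
    }
  }
  structure(
    list(
      sessions = sessions,
      ground_truth = tibble(
        p_correct_right = agent$p_correct_right,
        p_correct_left = agent$p_correct_left,
        laser_delta_contra = agent$laser_delta_contra,
        p_timeout = agent$p_timeout,
        expected_contra_action_delta =
          expected_contra_action_delta(agent, task, hemisphere)
      ),
      agent = agent,
      task = task
    ),
    class = "behavior_cohort"
  )
}

#' Analytic contraversive-action-bias change implied by agent parameters
#'
#' Computes the expected laser-induced change in contraversive action bias
#' directly from the generative probabilities: with `cc` the probability of
#' a correct choice on contra-cued trials and `ii` the probability of an
#' incorrect (i.e. contraversive) choice on ipsi-cued trials, the index is
#' `((cc_l + ii_l) - (cc_nl + ii_nl)) / (cc_nl + ii_nl)`, with the laser
#' shift applied (and clipped) exactly as the generator applies it. Used as
#' the closed-form expectation in recovery tests.
#'
#' @param agent An [agent_params()].
#' @param task A [task_config()].
#' @param hemisphere Analysis hemisphere.
#' @return The expected index (a single number).
#' @export
expected_contra_action_delta <- function(agent, task, hemisphere = "left") {
  p_contra_given <- function(cue, laser) {
    p_pos <- prob_positive_choice(cue, laser, agent, task$contingency,
                                  hemisphere)
    if (hemisphere == "left") p_pos else 1 - p_pos
  }
  contra_cue <- if (cue_action_class("right", task$contingency, hemisphere) ==
                    "contraversive") "right" else "left"
  ipsi_cue <- setdiff(c("left", "right"), contra_cue)
  cc_nl <- p_contra_given(contra_cue, FALSE)
  cc_l <- p_contra_given(contra_cue, TRUE)
  ii_nl <- p_contra_given(ipsi_cue, FALSE)
  ii_l <- p_contra_given(ipsi_cue, TRUE)
  as.numeric(((cc_l + ii_l) - (cc_nl + ii_nl)) / (cc_nl + ii_nl))
}
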