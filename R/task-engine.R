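#' Task configuration for the closed-loop trackball task
#'
#' Bundles the fixed parameters of the head-fixed two-alternative task in
#' which a mouse moves a lateralized visual cue by rotating a trackball.
#' Under the inward contingency the cue must be moved to the screen center
#' (a 15 degree ball rotation in the correct direction); under the outward
#' contingency it must be moved to the screen edge. Movements in the wrong
#' direction displace the cue the other way and must be offset, so outcome
#' classification is purely cumulative-angle based.
#'
#' Sign convention (declared once, used everywhere): positive cumulative
#' angle is the rotation that brings a right-side stimulus toward the screen
#' center in the inward task. For a left analysis hemisphere this is the
#' contraversive action.
#'
#' @param contingency `"inward"` or `"outward"`.
#' @param threshold_deg Rotation needed for a complete response (default 15).
#' @param response_window_s Time allowed for a response (default 1 s).
#' @param hold_still_s Hold-still period required to start a trial
#'   (default 1 s; simulated as dead time).
#' @param iti_s Inter-trial interval (default 2.5 s; dead time).
#' @param deg_per_pixel Ball calibration, degrees per optical-mouse pixel
#'   (default 0.15).
#' @param spontaneous_threshold_deg Movement threshold in no-cue sessions
#'   (default 5).
#' @param spontaneous_trial_s No-cue trial duration (default 2 s).
#' @param anti_bias Repeat the cue after errors until answered correctly?
#' @param laser_fraction Fraction of trials with optogenetic illumination,
#'   in \[0, 0.5\].
#' @param laser_window `(pre_s, post_s)` of illumination around cue onset
#'   (default `c(0.3, 1.0)`).
#' @param tick_s Ball sampling period (default 0.01 s).
#' @return A `task_config` list.
#' @export
task_config <- function(contingency = c("inward", "outward"),
                        threshold_deg = 15,
                        response_window_s = 1,
                        hold_still_s = 1,
                        iti_s = 2.5,
                        deg_per_pixel = 0.15,
                        spontaneous_threshold_deg = 5,
                        spontaneous_trial_s = 2,
                        anti_bias = FALSE,
                        laser_fraction = 0,
                        laser_window = c(0.3, 1.0),
                        tick_s = 0.01) {
  contingency <- match.arg(contingency)
  stopifnot(threshold_deg > 0, response_window_s > 0, hold_still_s >= 0,
            iti_s >= 0, spontaneous_threshold_deg > 0,
            spontaneous_trial_s > 0, tick_s > 0,
            laser_fraction >= 0, laser_fraction <= 0.5,
            length(laser_window) == 2, all(laser_window > 0))
  structure(
    list(
      contingency = contingency,
      threshold_deg = threshold_deg,
      response_window_s = response_window_s,
      hold_still_s = hold_still_s,
      iti_s = iti_s,
      deg_per_pixel = deg_per_pixel,
      spontaneous_threshold_deg = spontaneous_threshold_deg,
      spontaneous_trial_s = spontaneous_trial_s,
      anti_bias = anti_bias,
      laser_fraction = laser_fraction,
      laser_window = laser_window,
      tick_s = tick_s
    ),
    class = "task_config"
  )
}

# Direction (+/-) that is correct for a cue under a contingency.
# Inward: a right cue is answered by the positive rotation.
correct_direction <- function(cue_side, contingency) {
  pos_correct <- (cue_side == "right") == (contingency == "inward")
  if_else(pos_correct, "pos", "neg")
}

# Map a rotation direction to contraversive/ipsiversive given the analysis
# hemisphere. Positive rotation is contraversive for the left hemisphere.
direction_to_action <- function(direction, hemisphere) {
  contra_dir <- if_else(hemisphere == "left", "pos", "neg")
  if_else(direction == contra_dir, "contraversive", "ipsiversive")
}

# Cue class: is the correct action for this cue contraversive or ipsiversive?
cue_action_class <- function(cue_side, contingency, hemisphere) {
  direction_to_action(correct_direction(cue_side, contingency), hemisphere)
}

#' Classify a single-trial ball trace into an outcome
#'
#' Scans the cumulative ball angle from cue onset and finds the first time
#' it reaches `+threshold` or `-threshold` within the response window. The
#' crossing direction, the cue side, and the contingency determine
#' correct/incorrect; no crossing within the window is a timeout. Because
#' the angle is cumulative, wrong-direction excursions must be offset
#' before a correct response can register.
#'
#' @param trace A data frame with strictly increasing `time_s` (starting at
#'   cue onset, t = 0) and signed cumulative `angle_deg`.
#' @param cue_side `"left"` or `"right"`.
#' @param config A [task_config()].
#' @return A one-row tibble: `outcome` (`"correct"`, `"incorrect"`,
#'   `"timeout"`), `response_time_s` (NA on timeout), `chosen_direction`
#'   (`"pos"`, `"neg"`, or NA).
#' @export
classify_trial <- function(trace, cue_side, config) {
  stopifnot(is.data.frame(trace), all(c("time_s", "angle_deg") %in% names(trace)))
  t <- trace$time_s
  a <- trace$angle_deg
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop_bad_arg("trace times must be strictly increasing")
  }
  if (any(!is.finite(a))) {
    stop_bad_arg("trace angles must be finite")
  }
  in_window <- t <= config$response_window_s
  thr <- config$threshold_deg
  hit <- which(in_window & abs(a) >= thr)
  if (length(hit) == 0) {
    return(tibble(outcome = "timeout", response_time_s = NA_real_,
                  chosen_direction = NA_character_))
  }
  first <- hit[1]
  dir <- if (a[first] >= thr) "pos" else "neg"
  outcome <- if (dir == correct_direction(cue_side, config$contingency)) {
    "correct"
  } else {
    "incorrect"
  }
  tibble(outcome = outcome, response_time_s = t[first],
         chosen_direction = dir)
}

#' Anti-bias cue scheduling
#'
#' After an error (incorrect or timeout) the same cue is repeated until the
#' animal answers it correctly; after a correct trial the next cue is drawn
#' uniformly at random.
#'
#' @param prev_cue `"left"` or `"right"`.
#' @param prev_outcome Outcome of the previous trial.
#' @return The next cue side.
#' @export
anti_bias_next_cue <- function(prev_cue, prev_outcome) {
  if (prev_outcome == "correct") {
    sample(c("left", "right"), 1)
  } else {
    prev_cue
  }
}

#' Schedule laser trials with a no-consecutive constraint
#'
#' Selects `round(fraction * n_trials)` trials for optogenetic illumination
#' such that no two scheduled trials are adjacent (a minimum of `min_gap`
#' unscheduled trials separates any two). The subset is drawn uniformly at
#' random among all subsets satisfying the constraint, so the realized
#' fraction equals the target exactly (up to rounding).
#'
#' @param n_trials Number of trials.
#' @param fraction Target laser fraction, in \[0, 0.5\].
#' @param min_gap Minimum number of non-laser trials between laser trials
#'   (default 1, i.e. never two in a row).
#' @param seed Optional integer seed.
#' @return A logical vector of length `n_trials`.
#' @export
laser_schedule <- function(n_trials, fraction, min_gap = 1, seed = NULL) {
  stopifnot(n_trials >= 1, min_gap >= 1)
  if (fraction < 0 || fraction > 0.5) {
    stop_bad_arg("laser fraction must lie in [0, 0.5]")
  }
  k <- round(fraction * n_trials)
  out <- rep(FALSE, n_trials)
  if (k == 0) {
    return(out)
  }
  slots <- n_trials - (k - 1) * min_gap
  if (slots < k) {
    stop_bad_arg("laser fraction unsatisfiable under the gap constraint")
  }
  pos <- with_seed(seed, sort(sample.int(slots, k)) + (seq_len(k) - 1) * min_gap)
  out[pos] <- TRUE
  out
}

new_session_log <- function(mouse_id, hemisphere, contingency, trials,
                            config, seed = NULL, kind = "task",
                            metadata = list()) {
  structure(
    list(
      mouse_id = mouse_id,
      hemisphere = hemisphere,
      contingency = contingency,
      kind = kind,
      trials = trials,
      config = config,
      seed = seed,
      metadata = metadata
    ),
    class = "session_log"
  )
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("Session log: mouse %s, %s hemisphere, %s %s, %d trials\n",
              x$mouse_id, x$hemisphere, x$contingency, x$kind,
              nrow(x$trials)))
  if (x$kind == "task") {
    tab <- table(x$trials$outcome)
    cat("  outcomes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

validate_trace <- function(trace, config) {
  dt <- diff(trace$time_s)
  if (length(dt) && (any(dt <= 0) || any(dt > 10 * config$tick_s))) {
    stop_bad_arg("agent trace violates the ball tick spacing")
  }
  trace
}

#' Run a closed-loop task session
#'
#' Binds an agent policy to the task engine: per trial, a cue side is drawn
#' (uniformly, or by the anti-bias rule), the laser schedule is consulted,
#' the agent produces a ball trace, and the trace is classified into an
#' outcome. Hold-to-start and the inter-trial interval are simulated as
#' dead time advancing the session clock. Deterministic for a fixed seed
#' and deterministic agent.
#'
#' @param agent_policy Function `(cue_side, laser) -> trace` returning a
#'   data frame with `time_s` and `angle_deg` columns (t = 0 at cue onset).
#' @param config A [task_config()].
#' @param n_trials Number of trials.
#' @param seed Optional integer seed.
#' @param mouse_id,hemisphere Session identity (defaults `"m1"`, `"left"`).
#' @return A `session_log`: trial tibble with per-trial onset time, cue,
#'   laser flag, outcome, response time, chosen direction, and the trace as
#'   a list column.
#' @export
run_session <- function(agent_policy, config, n_trials, seed = NULL,
                        mouse_id = "m1", hemisphere = "left") {
  stopifnot(n_trials >= 1)
  with_seed(seed, {
    laser <- laser_schedule(n_trials, config$laser_fraction)
    rows <- vector("list", n_trials)
    clock <- 0
    cue <- sample(c("left", "right"), 1)
    for (i in seq_len(n_trials)) {
      clock <- clock + config$hold_still_s
      trace <- validate_trace(agent_policy(cue, laser[i]), config)
      cls <- classify_trial(trace, cue, config)
      rows[[i]] <- tibble(
        trial = i,
        onset_time_s = clock,
        cue_side = cue,
        laser = laser[i],
        outcome = cls$outcome,
        response_time_s = cls$response_time_s,
        chosen_direction = cls$chosen_direction,
        trace = list(as_tibble(trace))
      )
      elapsed <- if (is.na(cls$response_time_s)) {
        config$response_window_s
      } else {
        cls$response_time_s
      }
      clock <- clock + elapsed + config$iti_s
      cue <- if (config$anti_bias) {
        anti_bias_next_cue(cue, cls$outcome)
      } else {
        sample(c("left", "right"), 1)
      }
    }
    new_session_log(mouse_id, hemisphere, config$contingency,
                    bind_rows(rows), config, seed)
  })
}

#' Run a spontaneous (no-cue) session
#'
#' Back-to-back 2 s "trials" with no sensory cues. Each trial has a
#' software-designated rewarded direction; the animal earns a reward by
#' rotating the ball 5 degrees in that direction within the trial. Two
#' anti-bias rules run together: the designated direction repeats after an
#' unrewarded trial and switches after a rewarded one. Any 5-degree
#' crossing is recorded as an attempted movement with its direction,
#' rewarded or not.
#'
#' @param agent_policy Function `(cue_side, laser) -> trace`; called with
#'   `cue_side = NA` since no cue is shown.
#' @param config A [task_config()].
#' @param n_trials Number of 2 s trials.
#' @param seed Optional integer seed.
#' @param mouse_id,hemisphere Session identity.
#' @return A `session_log` with `kind = "spontaneous"`; per trial the
#'   designated direction, laser flag, movement direction (or NA), and
#'   reward flag.
#' @export
spontaneous_session <- function(agent_policy, config, n_trials, seed = NULL,
                                mouse_id = "m1", hemisphere = "left") {
  stopifnot(n_trials >= 1)
  with_seed(seed, {
    laser <- laser_schedule(n_trials, config$laser_fraction)
    thr <- config$spontaneous_threshold_deg
    rows <- vector("list", n_trials)
    designated <- sample(c("pos", "neg"), 1)
    for (i in seq_len(n_trials)) {
      trace <- validate_trace(agent_policy(NA_character_, laser[i]), config)
      in_win <- trace$time_s <= config$spontaneous_trial_s
      hit <- which(in_win & abs(trace$angle_deg) >= thr)
      moved_dir <- if (length(hit) == 0) {
        NA_character_
      } else if (trace$angle_deg[hit[1]] >= thr) {
        "pos"
      } else {
        "neg"
      }
      rewarded <- !is.na(moved_dir) && moved_dir == designated
      rows[[i]] <- tibble(
        trial = i,
        onset_time_s = (i - 1) * config$spontaneous_trial_s,
        designated_direction = designated,
        laser = laser[i],
        movement_direction = moved_dir,
        rewarded = rewarded,
        trace = list(as_tibble(trace))
      )
      designated <- if (rewarded) {
        setdiff(c("pos", "neg"), designated)
      } else {
        designated
      }
    }
    new_session_log(mouse_id, hemisphere, config$contingency,
                    bind_rows(rows), config, seed, kind = "spontaneous")
  })
}
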