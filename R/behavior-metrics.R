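#' Per-condition behavioral performance summary
#'
#' Tabulates performance for each cue side by laser condition. The timeout
#' rate uses all trials of that cue as denominator; the incorrect (and
#' correct) rate uses completed trials only, since timeouts are excluded
#' from accuracy and quantified separately. Mean response time is taken
#' over complete correct responses. Each cue is additionally labeled
#' contraversive- or ipsiversive-cued from the contingency and the analysis
#' hemisphere.
#'
#' @param trials A `session_log`, or a trial tibble with `cue_side`,
#'   `laser`, `outcome`, `response_time_s`.
#' @param contingency,hemisphere Required when `trials` is a bare tibble;
#'   taken from the log otherwise.
#' @return A tibble with one row per cue x laser cell: counts, `timeout_rate`,
#'   `incorrect_rate`, `correct_rate`, `mean_rt_s`, `cue_class`, and a
#'   `rates_defined` flag (FALSE when the cell has no completed trials).
#' @export
performance_summary <- function(trials, contingency = NULL,
                                hemisphere = NULL) {
  if (inherits(trials, "session_log")) {
    contingency <- contingency %||% trials$contingency
    hemisphere <- hemisphere %||% trials$hemisphere
    trials <- trials$trials
  }
  stopifnot(!is.null(contingency), !is.null(hemisphere),
            all(c("cue_side", "laser", "outcome") %in% names(trials)))
  out <- trials |>
    group_by(.data$cue_side, .data$laser) |>
    summarise(
      n_trials = dplyr::n(),
      n_timeout = sum(.data$outcome == "timeout"),
      n_completed = sum(.data$outcome != "timeout"),
      n_correct = sum(.data$outcome == "correct"),
      n_incorrect = sum(.data$outcome == "incorrect"),
      mean_rt_s = mean(.data$response_time_s[.data$outcome == "correct"]),
      .groups = "drop"
    ) |>
    mutate(
      timeout_rate = .data$n_timeout / .data$n_trials,
      incorrect_rate = if_else(.data$n_completed > 0,
                               .data$n_incorrect / .data$n_completed,
                               NA_real_),
      correct_rate = if_else(.data$n_completed > 0,
                             .data$n_correct / .data$n_completed,
                             NA_real_),
      rates_defined = .data$n_completed > 0,
      cue_class = cue_action_class(.data$cue_side, contingency, hemisphere)
    )
  attr(out, "contingency") <- contingency
  attr(out, "hemisphere") <- hemisphere
  out
}

#' Side preference index
#'
#' `(contraversive - ipsiversive) / (contraversive + ipsiversive)` where the
#' two terms are the proportions of contra- and ipsi-cued completed trials
#' answered correctly. +1 means the animal only gets contraversive-cued
#' trials right; 0 means no preference.
#'
#' @param perf A [performance_summary()] tibble (typically of non-laser
#'   trials).
#' @return A single number in \[-1, 1\]; NA with a warning when both
#'   proportions are zero.
#' @export
side_preference <- function(perf) {
  rate_of <- function(class) {
    rows <- perf[perf$cue_class == class, ]
    if (nrow(rows) == 0 || !any(rows$rates_defined)) {
      return(NA_real_)
    }
    sum(rows$n_correct) / sum(rows$n_completed)
  }
  contra <- rate_of("contraversive")
  ipsi <- rate_of("ipsiversive")
  if (is.na(contra) || is.na(ipsi)) {
    stop_bad_arg("correct-selection proportions undefined for a side")
  }
  if (contra + ipsi == 0) {
    warn("both correct-selection proportions are zero; preference undefined")
    return(NA_real_)
  }
  (contra - ipsi) / (contra + ipsi)
}

# Pull a correct/incorrect rate for a given selector from a performance
# summary, pooling counts across the matching rows of one laser condition.
pooled_rate <- function(perf, laser, select, type) {
  rows <- perf[perf$laser == laser & select(perf), ]
  completed <- sum(rows$n_completed)
  if (completed == 0) {
    return(NA_real_)
  }
  k <- if (type == "correct") sum(rows$n_correct) else sum(rows$n_incorrect)
  k / completed
}

#' Laser-induced bias index
#'
#' Relative laser-induced change in a summed pair of rates. In
#' `"contra_action"` mode the pair is the correct rate on
#' contraversive-cued trials plus the incorrect rate on ipsiversive-cued
#' trials (both are contraversive choices), indexing the change in
#' contraversive action bias. In `"right_stimulus"` mode the pair is the
#' correct rate on right-cue trials plus the incorrect rate on left-cue
#' trials (both are responses-as-if-right-stimulus), indexing the change in
#' right stimulus response bias; this form applies identically to inward
#' and outward sessions. Rates exclude timeouts by construction.
#'
#' @param perf A [performance_summary()] tibble covering both laser
#'   conditions.
#' @param mode `"contra_action"` or `"right_stimulus"`.
#' @return `((pair_laser) - (pair_nonlaser)) / (pair_nonlaser)`.
#' @export
laser_delta_index <- function(perf, mode = c("contra_action",
                                             "right_stimulus")) {
  mode <- match.arg(mode)
  if (mode == "contra_action") {
    sel_a <- function(p) p$cue_class == "contraversive"
    sel_b <- function(p) p$cue_class == "ipsiversive"
  } else {
    sel_a <- function(p) p$cue_side == "right"
    sel_b <- function(p) p$cue_side == "left"
  }
  pair <- function(laser) {
    a <- pooled_rate(perf, laser, sel_a, "correct")
    b <- pooled_rate(perf, laser, sel_b, "incorrect")
    a + b
  }
  num_l <- pair(TRUE)
  num_nl <- pair(FALSE)
  if (any(is.na(c(num_l, num_nl)))) {
    stop_bad_arg("all four constituent rates must be defined")
  }
  if (num_nl == 0) {
    stop_bad_arg("non-laser rate pair is zero; index undefined")
  }
  (num_l - num_nl) / num_nl
}

#' Attempt proportions in spontaneous sessions
#'
#' Counts attempted movements (5-degree threshold crossings, rewarded or
#' not) in a spontaneous session and returns, for each laser condition, the
#' proportion of attempts that were contraversive and ipsiversive relative
#' to the analysis hemisphere.
#'
#' @param session A spontaneous `session_log` (or its trial tibble plus
#'   `hemisphere`).
#' @param hemisphere Analysis hemisphere when passing a bare tibble.
#' @return A tibble with one row per laser condition: `n_attempts`,
#'   `contraversive`, `ipsiversive` (proportions summing to 1).
#' @export
spontaneous_rates <- function(session, hemisphere = NULL) {
  if (inherits(session, "session_log")) {
    hemisphere <- hemisphere %||% session$hemisphere
    session <- session$trials
  }
  stopifnot(!is.null(hemisphere),
            all(c("laser", "movement_direction") %in% names(session)))
  session |>
    filter(!is.na(.data$movement_direction)) |>
    mutate(action = direction_to_action(.data$movement_direction,
                                        hemisphere)) |>
    group_by(.data$laser) |>
    summarise(
      n_attempts = dplyr::n(),
      contraversive = mean(.data$action == "contraversive"),
      ipsiversive = mean(.data$action == "ipsiversive"),
      .groups = "drop"
    )
}

#' Laser-induced change in spontaneous movement proportions
#'
#' Relative change `(x_laser - x_nonlaser) / x_nonlaser` of the
#' contraversive and ipsiversive attempt proportions between laser
#' conditions.
#'
#' @param rates A [spontaneous_rates()] tibble with both laser conditions.
#' @return A tibble with `delta_contraversive`, `delta_ipsiversive`.
#' @export
spontaneous_delta <- function(rates) {
  l <- rates[rates$laser, ]
  nl <- rates[!rates$laser, ]
  if (nrow(l) != 1 || nrow(nl) != 1) {
    stop_bad_arg("rates must contain exactly one row per laser condition")
  }
  if (nl$contraversive == 0 || nl$ipsiversive == 0) {
    stop_bad_arg("non-laser proportion is zero; delta undefined")
  }
  tibble(
    delta_contraversive = (l$contraversive - nl$contraversive) /
      nl$contraversive,
    delta_ipsiversive = (l$ipsiversive - nl$ipsiversive) / nl$ipsiversive
  )
}

#' Mean instantaneous ball velocity of a trial
#'
#' Mean of per-tick `|delta angle| / delta t` from movement start (first
#' sample with cumulative |angle| above `start_deg`, default 0.5 degrees)
#' until the first threshold crossing. Direction-agnostic.
#'
#' @param trace A trial trace (`time_s`, `angle_deg`).
#' @param threshold_deg Response threshold (e.g. 15).
#' @param start_deg Movement-start criterion (default 0.5).
#' @return Velocity in deg/s, or NA when the trace never passes the
#'   movement-start criterion or never reaches threshold.
#' @export
movement_velocity <- function(trace, threshold_deg, start_deg = 0.5) {
  a <- trace$angle_deg
  t <- trace$time_s
  start <- which(abs(a) > start_deg)[1]
  end <- which(abs(a) >= threshold_deg)[1]
  if (is.na(start) || is.na(end) || end <= start) {
    return(NA_real_)
  }
  idx <- start:end
  mean(abs(diff(a[idx])) / diff(t[idx]))
}

# Pooled laser-minus-nonlaser metric closures used by the permutation
# analysis; each takes the pooled trial tibble.
pooled_metric_fns <- function(contingency, hemisphere) {
  rate_metric <- function(side, stat) {
    force(side); force(stat)
    function(trials) {
      tr <- trials[trials$cue_side == side, ]
      per_laser <- function(l) {
        sub <- tr[tr$laser == l, ]
        switch(stat,
          incorrect = {
            comp <- sub$outcome != "timeout"
            if (!any(comp)) return(NA_real_)
            mean(sub$outcome[comp] == "incorrect")
          },
          timeout = mean(sub$outcome == "timeout"),
          rt = {
            ok <- sub$outcome == "correct"
            if (!any(ok)) return(NA_real_)
            mean(sub$response_time_s[ok])
          }
        )
      }
      per_laser(TRUE) - per_laser(FALSE)
    }
  }
  index_metric <- function(mode) {
    force(mode)
    function(trials) {
      perf <- performance_summary(trials, contingency, hemisphere)
      laser_delta_index(perf, mode)
    }
  }
  list(
    incorrect_right = rate_metric("right", "incorrect"),
    incorrect_left = rate_metric("left", "incorrect"),
    timeout_right = rate_metric("right", "timeout"),
    timeout_left = rate_metric("left", "timeout"),
    rt_right = rate_metric("right", "rt"),
    rt_left = rate_metric("left", "rt"),
    contra_action = index_metric("contra_action"),
    right_stimulus = index_metric("right_stimulus")
  )
}

#' Cohort-level optogenetic effect analysis
#'
#' Combines each mouse's sessions, computes the laser-induced change in the
#' incorrect rate, timeout rate, and response time for right- and left-cue
#' trials plus the contraversive-action and right-stimulus bias indices on
#' the trials pooled across animals, and tests each against an animal-wise
#' permutation null ([permutation_test_laser()]). Significance for the
#' cue-pair metrics uses the Bonferroni-adjusted per-comparison alpha
#' 0.05 / 2 = 0.025.
#'
#' @param cohort A `behavior_cohort` or a list of `session_log`s (multiple
#'   sessions per mouse are combined by `mouse_id`).
#' @param n_perm Permutation rounds per metric (default 1000).
#' @param seed Optional integer seed.
#' @param alpha Per-comparison significance level (default 0.025).
#' @return A `laser_effect_summary`: tibble with one row per metric
#'   (`metric`, `observed`, `p`, `significant`, `n_permutations`) plus the
#'   underlying `perm_test` objects.
#' @export
laser_effect_analysis <- function(cohort, n_perm = 1000, seed = NULL,
                                  alpha = bonferroni_alpha(0.05, 2)) {
  sessions <- if (inherits(cohort, "behavior_cohort")) {
    cohort$sessions
  } else {
    cohort
  }
  stopifnot(length(sessions) >= 1)
  ids <- vapply(sessions, function(s) s$mouse_id, character(1))
  if (length(unique(ids)) < 2) {
    stop_bad_arg("cohort analysis needs at least 2 mice")
  }
  contingency <- sessions[[1]]$contingency
  hemisphere <- sessions[[1]]$hemisphere
  keep_cols <- c("cue_side", "laser", "outcome", "response_time_s")
  per_animal <- lapply(split(sessions, ids), function(ss) {
    bind_rows(lapply(ss, function(s) s$trials[keep_cols]))
  })
  fns <- pooled_metric_fns(contingency, hemisphere)
  tests <- imap(fns, function(fn, name) {
    permutation_test_laser(per_animal, fn, n_perm = n_perm,
                           seed = child_seed(seed, match(name, names(fns))))
  })
  summary <- list_rbind(imap(tests, function(tst, name) {
    tibble(metric = name, observed = tst$observed_effect,
           p = tst$p_two_sided, significant = tst$p_two_sided < alpha,
           n_permutations = tst$n_permutations)
  }))
  structure(
    list(summary = summary, tests = tests, alpha = alpha,
         contingency = contingency, hemisphere = hemisphere,
         n_mice = length(per_animal)),
    class = "laser_effect_summary"
  )
}

#' @export
print.laser_effect_summary <- function(x, ...) {
  cat(sprintf("Laser effect analysis (%d mice, %s task, %s hemisphere)\n",
              x$n_mice, x$contingency, x$hemisphere))
  cat(sprintf("  per-comparison alpha (Bonferroni 0.05/2): %.3f\n", x$alpha))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.laser_effect_summary <- function(x, ...) {
  x$summary
}
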