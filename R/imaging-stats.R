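# Slice a ROIs x frames matrix around anchor times. Returns a list with the
# ROIs x events x frames array, the relative frame times, and the indices of
# events whose window fit inside the recording.
align_traces <- function(mat, frame_times, anchor_times, window,
                         frame_rate_hz) {
  stopifnot(length(window) == 2, window[1] < window[2])
  rel_frames <- seq(round(window[1] * frame_rate_hz),
                    round(window[2] * frame_rate_hz))
  rel_time_s <- rel_frames / frame_rate_hz
  anchor_idx <- vapply(anchor_times, function(tt) {
    which.min(abs(frame_times - tt))
  }, integer(1))
  ok <- anchor_idx + min(rel_frames) >= 1 &
    anchor_idx + max(rel_frames) <= length(frame_times)
  kept <- which(ok)
  arr <- array(NA_real_,
               dim = c(nrow(mat), length(kept), length(rel_frames)))
  for (j in seq_along(kept)) {
    cols <- anchor_idx[kept[j]] + rel_frames
    arr[, j, ] <- mat[, cols, drop = FALSE]
  }
  list(activity = arr, rel_time_s = rel_time_s, kept = kept)
}

#' Build a trial-aligned activity tensor
#'
#' Slices each ROI's (typically z-scored) session trace around a per-trial
#' anchor: the visual stimulus onset, or the response time. Completed
#' trials are labeled with one of four conditions from cue side x action
#' (contraversive/ipsiversive relative to the analysis hemisphere);
#' timeout trials carry no action and are excluded. Sessions with fewer
#' than `min_trials_per_condition` trials in any of the four conditions
#' are marked excluded (flag only; the tensor is still returned). Trials
#' whose window falls outside the recording are dropped and recorded in
#' `dropped_trials`.
#'
#' @param dff_obj A `dff_traces` object.
#' @param session The matching `session_log`.
#' @param anchor `"stimulus"` or `"response"`.
#' @param window Length-2 window in seconds around the anchor (defaults:
#'   `c(-1, 2)` for stimulus, `c(-0.2, 0.4)` for response).
#' @param min_trials_per_condition Inclusion rule (default 5).
#' @return A `trial_tensor`: `activity` (ROIs x trials x frames),
#'   `trials` tibble (cue, action, condition, velocity-ready fields),
#'   `rel_time_s`, `anchor`, `included`, `roi_labels`.
#' @export
build_trial_tensor <- function(dff_obj, session,
                               anchor = c("stimulus", "response"),
                               window = NULL,
                               min_trials_per_condition = 5) {
  stopifnot(inherits(dff_obj, "dff_traces"),
            inherits(session, "session_log"))
  anchor <- match.arg(anchor)
  window <- window %||% if (anchor == "stimulus") c(-1, 2) else c(-0.2, 0.4)
  trials <- session$trials
  completed <- filter(trials, .data$outcome != "timeout")
  anchor_times <- if (anchor == "stimulus") {
    completed$onset_time_s
  } else {
    completed$onset_time_s + completed$response_time_s
  }
  al <- align_traces(dff_obj$dff, dff_obj$frame_times, anchor_times,
                     window, dff_obj$frame_rate_hz)
  kept <- completed[al$kept, ]
  action <- direction_to_action(kept$chosen_direction, session$hemisphere)
  lab <- tibble(
    trial = kept$trial,
    cue_side = kept$cue_side,
    laser = kept$laser,
    action = action,
    condition = paste(kept$cue_side, ifelse(action == "contraversive",
                                            "contra", "ipsi"), sep = "-"),
    response_time_s = kept$response_time_s
  )
  counts <- table(factor(lab$condition,
                         levels = c("right-contra", "right-ipsi",
                                    "left-contra", "left-ipsi")))
  structure(
    list(
      activity = al$activity,
      trials = lab,
      rel_time_s = al$rel_time_s,
      anchor = anchor,
      window = window,
      included = all(counts >= min_trials_per_condition),
      condition_counts = counts,
      dropped_trials = setdiff(completed$trial, kept$trial),
      roi_labels = dff_obj$roi_labels,
      hemisphere = session$hemisphere,
      frame_rate_hz = dff_obj$frame_rate_hz
    ),
    class = "trial_tensor"
  )
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$activity)
  cat(sprintf("Trial tensor: %d ROIs x %d trials x %d frames (%s-aligned)\n",
              d[1], d[2], d[3], x$anchor))
  print(x$condition_counts)
  cat("  included (>= 5 trials/condition):", x$included, "\n")
  invisible(x)
}

# Per-trial scalar response: mean over frames with rel_time in (lo, hi].
window_mean <- function(tensor, lo, hi) {
  cols <- which(tensor$rel_time_s > lo & tensor$rel_time_s <= hi)
  if (length(cols) == 0) {
    stop_bad_arg("no frames in the requested window")
  }
  apply(tensor$activity[, , cols, drop = FALSE], c(1, 2), mean)
}

#' Task-condition statistics for each neuron and the population
#'
#' From a stimulus-aligned tensor, averages each neuron's z-scored
#' activity over the 1 s post-stimulus window per trial, then:
#' per neuron, the mean post-stimulus response in each of the four cue x
#' action conditions and the four marginals (each marginal is the average
#' of its two constituent condition means, so unequal trial counts do not
#' bias it); population-level contra-versus-ipsi contrasts within each cue
#' (paired signed-rank across neurons) and the marginal cue and action
#' contrasts; the per-neuron action-difference test (rank-sum across
#' trials within each cue at `alpha`) with an exact binomial CI on the
#' population fraction; and, when per-trial ball velocities are supplied,
#' a median-split comparison of high- versus low-velocity trials.
#'
#' @param tensor A stimulus-aligned `trial_tensor`.
#' @param velocities Optional numeric vector of per-trial ball velocities
#'   aligned to `tensor$trials`.
#' @param post_window Post-stimulus averaging window (default `c(0, 1)` s).
#' @param alpha Per-neuron test level (default 0.05).
#' @return A `neuron_task_stats` list: `per_neuron`, `contrasts`,
#'   `fraction_significant`, `velocity_split` tibbles.
#' @export
neuron_condition_stats <- function(tensor, velocities = NULL,
                                   post_window = c(0, 1), alpha = 0.05) {
  stopifnot(inherits(tensor, "trial_tensor"), tensor$anchor == "stimulus")
  resp <- window_mean(tensor, post_window[1], post_window[2])
  lab <- tensor$trials
  n_roi <- nrow(resp)
  cond_mean <- function(cond) {
    idx <- which(lab$condition == cond)
    if (length(idx) == 0) {
      return(rep(NA_real_, n_roi))
    }
    rowMeans(resp[, idx, drop = FALSE])
  }
  rc <- cond_mean("right-contra"); ri <- cond_mean("right-ipsi")
  lc <- cond_mean("left-contra"); li <- cond_mean("left-ipsi")
  per_neuron <- tibble(
    roi = seq_len(n_roi),
    roi_label = tensor$roi_labels,
    right_contra = rc, right_ipsi = ri,
    left_contra = lc, left_ipsi = li,
    right_cue = (rc + ri) / 2, left_cue = (lc + li) / 2,
    contra = (rc + lc) / 2, ipsi = (ri + li) / 2
  )
  contrast <- function(a, b, name) {
    ok <- complete.cases(a, b)
    res <- tryCatch(rank_tests(a[ok], b[ok], paired = TRUE),
                    orientrack_error = function(e) tibble(p = NA_real_,
                                                          z = NA_real_))
    tibble(contrast = name, p = res$p, z = res$z, n_neurons = sum(ok))
  }
  contrasts <- bind_rows(
    contrast(rc, ri, "right_cue_contra_vs_ipsi"),
    contrast(lc, li, "left_cue_contra_vs_ipsi"),
    contrast(per_neuron$right_cue, per_neuron$left_cue,
             "right_vs_left_cue"),
    contrast(per_neuron$contra, per_neuron$ipsi, "contra_vs_ipsi_action")
  )
  # per-neuron across-trial action difference, within each cue
  sig_action <- function(cue) {
    a_idx <- which(lab$cue_side == cue & lab$action == "contraversive")
    b_idx <- which(lab$cue_side == cue & lab$action == "ipsiversive")
    vapply(seq_len(n_roi), function(i) {
      if (length(a_idx) < 2 || length(b_idx) < 2) {
        return(NA)
      }
      res <- tryCatch(rank_tests(resp[i, a_idx], resp[i, b_idx]),
                      orientrack_error = function(e) NULL)
      if (is.null(res)) NA else res$p < alpha
    }, logical(1))
  }
  frac_row <- function(cue) {
    sig <- sig_action(cue)
    n_ok <- sum(!is.na(sig))
    if (n_ok == 0) {
      return(tibble(cue_side = cue, n_significant = 0L, n_neurons = 0L,
                    fraction = NA_real_, lo = NA_real_, hi = NA_real_))
    }
    k <- sum(sig, na.rm = TRUE)
    ci <- binomial_ci(k, n_ok)
    tibble(cue_side = cue, n_significant = k, n_neurons = n_ok,
           fraction = ci$estimate, lo = ci$lo, hi = ci$hi)
  }
  fraction_significant <- bind_rows(frac_row("right"), frac_row("left"))
  velocity_split <- NULL
  if (!is.null(velocities)) {
    stopifnot(length(velocities) == nrow(lab))
    ok <- !is.na(velocities)
    med <- median(velocities[ok])
    hi_idx <- which(ok & velocities > med)
    lo_idx <- which(ok & velocities <= med)
    hi_mean <- rowMeans(resp[, hi_idx, drop = FALSE])
    lo_mean <- rowMeans(resp[, lo_idx, drop = FALSE])
    res <- tryCatch(rank_tests(hi_mean, lo_mean, paired = TRUE),
                    orientrack_error = function(e) tibble(p = NA_real_,
                                                          z = NA_real_))
    velocity_split <- tibble(
      median_velocity = med, n_high = length(hi_idx),
      n_low = length(lo_idx),
      mean_high = mean(hi_mean), mean_low = mean(lo_mean),
      p = res$p, z = res$z
    )
  }
  structure(
    list(per_neuron = per_neuron, contrasts = contrasts,
         fraction_significant = fraction_significant,
         velocity_split = velocity_split, alpha = alpha),
    class = "neuron_task_stats"
  )
}

#' @export
print.neuron_task_stats <- function(x, ...) {
  cat("Task-condition statistics,", nrow(x$per_neuron), "neurons\n")
  print(x$contrasts)
  print(x$fraction_significant)
  invisible(x)
}

#' @export
tidy.neuron_task_stats <- function(x, ...) {
  x$per_neuron
}

#' Visual responsiveness and stimulus preference of boutons
#'
#' For each bouton in a passive-viewing recording: tests responsiveness by
#' comparing pre-stimulus activity (1 s average) against activity averaged
#' 0.6-1.2 s after stimulus onset (two-sided signed-rank across trials,
#' `p < alpha_responsive`, default 0.01); computes the AUROC between
#' per-trial responses on contralateral versus ipsilateral stimulus trials
#' for responsive boutons and maps it to a preference score
#' `2 * (AUROC - 0.5)`; and tests the score against a null built by
#' shuffling trial labels, calling it significant outside the central 95%
#' of the shuffled distribution. Boutons with fewer than 2 trials per side
#' are excluded.
#'
#' @param dff_obj A `dff_traces` object (bouton ROIs).
#' @param stim_table A tibble with `onset_time_s` and `side`
#'   (`"contra"`/`"ipsi"`) per stimulus presentation.
#' @param n_shuffles Label shuffles per bouton (default 1000).
#' @param alpha_responsive Responsiveness level (default 0.01).
#' @param seed Optional integer seed.
#' @param response_window Post-stimulus response window (default
#'   `c(0.6, 1.2)` s).
#' @return A `bouton_visual_stats` list: `per_bouton` tibble (`responsive`,
#'   `auroc`, `preference_score`, `preference_significant`, null bounds)
#'   and a `population` tibble of preferring-bouton counts.
#' @export
bouton_visual_stats <- function(dff_obj, stim_table, n_shuffles = 1000,
                                alpha_responsive = 0.01, seed = NULL,
                                response_window = c(0.6, 1.2)) {
  stopifnot(inherits(dff_obj, "dff_traces"),
            all(c("onset_time_s", "side") %in% names(stim_table)))
  al <- align_traces(dff_obj$dff, dff_obj$frame_times,
                     stim_table$onset_time_s, c(-1, response_window[2]),
                     dff_obj$frame_rate_hz)
  side <- stim_table$side[al$kept]
  rel <- al$rel_time_s
  pre_cols <- which(rel >= -1 & rel < 0)
  post_cols <- which(rel > response_window[1] & rel <= response_window[2])
  pre <- apply(al$activity[, , pre_cols, drop = FALSE], c(1, 2), mean)
  post <- apply(al$activity[, , post_cols, drop = FALSE], c(1, 2), mean)
  n_roi <- nrow(pre)
  contra_idx <- which(side == "contra")
  ipsi_idx <- which(side == "ipsi")
  rows <- map(seq_len(n_roi), function(i) {
    if (length(contra_idx) < 2 || length(ipsi_idx) < 2) {
      return(tibble(roi = i, excluded = TRUE, responsive = NA,
                    auroc = NA_real_, preference_score = NA_real_,
                    preference_significant = NA, null_lo = NA_real_,
                    null_hi = NA_real_, p_responsive = NA_real_))
    }
    res <- tryCatch(rank_tests(post[i, ], pre[i, ], paired = TRUE),
                    orientrack_error = function(e) tibble(p = 1))
    responsive <- res$p < alpha_responsive
    if (!isTRUE(responsive)) {
      return(tibble(roi = i, excluded = FALSE, responsive = FALSE,
                    auroc = NA_real_, preference_score = NA_real_,
                    preference_significant = NA, null_lo = NA_real_,
                    null_hi = NA_real_, p_responsive = res$p))
    }
    sh <- shuffle_significance(
      post[i, contra_idx], post[i, ipsi_idx],
      function(a, b) preference_score(auroc(a, b)),
      n_shuffles = n_shuffles, seed = child_seed(seed, i)
    )
    tibble(roi = i, excluded = FALSE, responsive = TRUE,
           auroc = auroc(post[i, contra_idx], post[i, ipsi_idx]),
           preference_score = sh$observed,
           preference_significant = sh$significant,
           null_lo = sh$null_lo, null_hi = sh$null_hi,
           p_responsive = res$p)
  })
  per_bouton <- list_rbind(rows)
  resp <- per_bouton[per_bouton$responsive %in% TRUE, ]
  population <- tibble(
    n_responsive = sum(per_bouton$responsive %in% TRUE),
    n_contra_preferring = sum(resp$preference_significant %in% TRUE &
                                resp$preference_score > 0),
    n_ipsi_preferring = sum(resp$preference_significant %in% TRUE &
                              resp$preference_score < 0)
  )
  structure(
    list(per_bouton = per_bouton, population = population,
         n_shuffles = n_shuffles, alpha_responsive = alpha_responsive),
    class = "bouton_visual_stats"
  )
}

#' @export
print.bouton_visual_stats <- function(x, ...) {
  cat("Bouton visual statistics,", nrow(x$per_bouton), "boutons\n")
  print(x$population)
  invisible(x)
}

#' @export
tidy.bouton_visual_stats <- function(x, ...) {
  x$per_bouton
}

#' Compare preferring-bouton proportions between two populations
#'
#' Builds the 2x2 table (preferring vs not, population A vs B) and runs
#' the log-space two-sided Fisher exact test, as used to compare the
#' fractions of contra-preferring boutons between two input pathways.
#'
#' @param k_a,n_a Preferring count and total for population A.
#' @param k_b,n_b Same for population B.
#' @return The [fisher_exact_two_sided()] tibble plus both proportions and
#'   their exact binomial CIs.
#' @export
compare_preference_populations <- function(k_a, n_a, k_b, n_b) {
  fisher <- fisher_exact_two_sided(c(k_a, n_a - k_a, k_b, n_b - k_b))
  ci_a <- binomial_ci(k_a, n_a)
  ci_b <- binomial_ci(k_b, n_b)
  tibble(
    prop_a = ci_a$estimate, lo_a = ci_a$lo, hi_a = ci_a$hi,
    prop_b = ci_b$estimate, lo_b = ci_b$lo, hi_b = ci_b$hi,
    log10_p = fisher$log10_p, p = fisher$p
  )
}
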