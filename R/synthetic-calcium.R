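#' Parameters for the synthetic calcium imaging generator
#'
#' Describes a GCaMP6s-like linear-kernel generative model sampled at 5 Hz.
#' Each neuron carries tuning weights for the cue side (impulse at stimulus
#' onset) and the action direction (impulse at the response); weights are
#' convolved with a rise/decay kernel (decay ~1.5 s, indicator-like).
#' Measured soma fluorescence is the clean signal plus
#' `neuropil_coefficient` times the neuropil trace, a multiplicative slow
#' drift (linear component plus slow sinusoid plus a gentle random walk),
#' and Gaussian noise - so subtracting `0.7 x neuropil` removes the
#' contamination by construction and the drift/detrending interplay is
#' testable.
#'
#' @param n_neurons Number of ROIs.
#' @param frac_labeled Fraction tagged as projection-labeled.
#' @param cue_weight_sd SD of per-neuron cue weights (DFF fraction units).
#' @param action_weight_sd SD of per-neuron action weights.
#' @param action_ipsi_bias Mean added to the ipsiversive action weight
#'   (positive values emulate ipsi-preferring populations).
#' @param labeled_action_gain Multiplier on action weights of labeled
#'   neurons (2 emulates a more action-informative subpopulation).
#' @param rise_s,decay_s Kernel time constants (defaults 0.2, 1.5 s).
#' @param baseline_f,neuropil_f Raw baseline fluorescence of soma and
#'   neuropil.
#' @param neuropil_coefficient Contamination coefficient injected (0.7).
#' @param drift_linear_frac Fractional linear drift per 10 minutes
#'   (default 0.2).
#' @param drift_sin_amp,drift_period_s Slow sinusoidal drift (default
#'   amplitude 0.05, period 300 s).
#' @param drift_rw_sd Per-second SD of the random-walk drift component
#'   (default 0.002; 0 disables it).
#' @param noise_sd Gaussian noise SD as a fraction of baseline
#'   (default 0.02).
#' @param frame_rate_hz Imaging rate (default 5).
#' @return A `calcium_sim_params` list.
#' @export
calcium_sim_params <- function(n_neurons = 100, frac_labeled = 0.3,
                               cue_weight_sd = 0.3, action_weight_sd = 0.3,
                               action_ipsi_bias = 0,
                               labeled_action_gain = 1,
                               rise_s = 0.2, decay_s = 1.5,
                               baseline_f = 100, neuropil_f = 50,
                               neuropil_coefficient = 0.7,
                               drift_linear_frac = 0.2,
                               drift_sin_amp = 0.05, drift_period_s = 300,
                               drift_rw_sd = 0.002,
                               noise_sd = 0.02, frame_rate_hz = 5) {
  stopifnot(n_neurons >= 1, frac_labeled >= 0, frac_labeled <= 1,
            decay_s > rise_s, rise_s > 0, frame_rate_hz > 0,
            drift_period_s >= 100, baseline_f > 0)
  structure(as.list(environment()), class = "calcium_sim_params")
}

# Difference-of-exponentials kernel sampled on the frame grid, peak 1.
calcium_kernel <- function(rise_s, decay_s, frame_rate_hz) {
  t <- seq(0, 6 * decay_s, by = 1 / frame_rate_hz)
  k <- exp(-t / decay_s) - exp(-t / rise_s)
  k / max(k)
}

# Convolve per-frame impulses with the kernel (causal).
convolve_impulses <- function(impulses, kernel) {
  out <- stats::convolve(impulses, rev(kernel), type = "open")
  out[seq_along(impulses)]
}

drift_curve <- function(n_frames, frame_rate_hz, params) {
  t <- (seq_len(n_frames) - 1) / frame_rate_hz
  rw <- cumsum(rnorm(n_frames, 0, params$drift_rw_sd / sqrt(frame_rate_hz)))
  1 + params$drift_linear_frac * t / 600 +
    params$drift_sin_amp * sin(2 * pi * t / params$drift_period_s) + rw
}

#' Simulate a calcium imaging session tied to a behavioral session
#'
#' Generates raw soma and neuropil fluorescence matrices for a
#' [run_session()] log under the [calcium_sim_params()] model, together
#' with the ground-truth tuning table and the noiseless percent-DFF signal
#' for round-trip tests. Cue-tuned impulses occur at stimulus onsets and
#' action-tuned impulses at response times of completed trials.
#'
#' @param session A `session_log`.
#' @param params A [calcium_sim_params()].
#' @param seed Optional integer seed.
#' @param tail_s Recording time appended after the last trial (default 20 s,
#'   plus enough to satisfy detrending).
#' @return A list: `traces` ([roi_trace_set()]), `ground_truth` (tibble of
#'   per-neuron weights and labels), `true_dff` (noiseless percent DFF),
#'   `session`.
#' @export
simulate_calcium_session <- function(session, params = calcium_sim_params(),
                                     seed = NULL, tail_s = 20) {
  stopifnot(inherits(session, "session_log"))
  with_seed(seed, {
    fr <- params$frame_rate_hz
    trials <- session$trials
    dur <- max(trials$onset_time_s) + tail_s
    dur <- max(dur, 90)  # leave room for the 60 s detrending window
    n_frames <- ceiling(dur * fr)
    frame_times <- (seq_len(n_frames) - 1) / fr
    n <- params$n_neurons
    labeled <- runif(n) < params$frac_labeled
    gt <- tibble(
      roi = seq_len(n),
      labeled = labeled,
      w_cue_right = abs(rnorm(n, 0, params$cue_weight_sd)),
      w_cue_left = abs(rnorm(n, 0, params$cue_weight_sd)),
      w_act_contra = abs(rnorm(n, 0, params$action_weight_sd)) *
        if_else(labeled, params$labeled_action_gain, 1),
      w_act_ipsi = (abs(rnorm(n, 0, params$action_weight_sd)) +
                      params$action_ipsi_bias) *
        if_else(labeled, params$labeled_action_gain, 1)
    )
    kernel <- calcium_kernel(params$rise_s, params$decay_s, fr)
    onset_frame <- pmin(n_frames, round(trials$onset_time_s * fr) + 1)
    completed <- !is.na(trials$response_time_s)
    resp_frame <- pmin(n_frames, round((trials$onset_time_s +
      if_else(completed, trials$response_time_s, 0)) * fr) + 1)
    action <- direction_to_action(trials$chosen_direction,
                                  session$hemisphere)
    true_dff <- matrix(0, n, n_frames)
    for (i in seq_len(n)) {
      imp <- numeric(n_frames)
      cue_w <- if_else(trials$cue_side == "right",
                       gt$w_cue_right[i], gt$w_cue_left[i])
      act_w <- if_else(action == "contraversive",
                       gt$w_act_contra[i], gt$w_act_ipsi[i])
      for (j in seq_len(nrow(trials))) {
        imp[onset_frame[j]] <- imp[onset_frame[j]] + cue_w[j]
        if (completed[j]) {
          imp[resp_frame[j]] <- imp[resp_frame[j]] + act_w[j]
        }
      }
      true_dff[i, ] <- convolve_impulses(imp, kernel)
    }
    common <- gaussian_smooth_rows(
      matrix(colMeans(true_dff), 1), fr, 2)[1, ]
    neuropil_raw <- soma_raw <- matrix(0, n, n_frames)
    for (i in seq_len(n)) {
      drift <- drift_curve(n_frames, fr, params)
      npil <- params$neuropil_f *
        (1 + 0.5 * common + rnorm(n_frames, 0, params$noise_sd))
      clean <- params$baseline_f * (1 + true_dff[i, ]) * drift
      neuropil_raw[i, ] <- npil
      soma_raw[i, ] <- clean + params$neuropil_coefficient * npil +
        rnorm(n_frames, 0, params$noise_sd * params$baseline_f)
    }
    list(
      traces = roi_trace_set(
        soma_raw, neuropil_raw, frame_times,
        roi_labels = if_else(labeled, "labeled", "unlabeled")
      ),
      ground_truth = gt,
      true_dff = 100 * true_dff,
      session = session
    )
  })
}

#' Simulate passive-viewing bouton recordings
#'
#' Generates bouton fluorescence traces for a passive stimulation protocol
#' (1 s lateralized stimuli with randomized sides) in which each bouton
#' prefers the contralateral side with probability `contra_frac` and
#' responds to its preferred side with amplitude `effect_size` larger than
#' to the other side.
#'
#' @param n_boutons Number of boutons.
#' @param contra_frac Probability a bouton prefers contra stimuli.
#' @param effect_size Preferred-minus-nonpreferred response amplitude, in
#'   DFF fraction units (0 = no tuning; responses to both sides equal).
#' @param n_trials_per_side Stimulus repeats per side (default 20).
#' @param base_amp Response amplitude to the non-preferred side
#'   (default 0.3).
#' @param params A [calcium_sim_params()] supplying kernel, noise, and
#'   frame-rate settings (neuropil and drift are not applied to boutons).
#' @param seed Optional integer seed.
#' @return A list: `traces` (bouton [roi_trace_set()]), `stim_table`
#'   (`onset_time_s`, `side`), `ground_truth` (per-bouton preferred side).
#' @export
simulate_bouton_passive <- function(n_boutons = 100, contra_frac = 0.5,
                                    effect_size = 1, n_trials_per_side = 20,
                                    base_amp = 0.3,
                                    params = calcium_sim_params(),
                                    seed = NULL) {
  stopifnot(contra_frac >= 0, contra_frac <= 1, n_trials_per_side >= 2)
  with_seed(seed, {
    fr <- params$frame_rate_hz
    n_stim <- 2 * n_trials_per_side
    side <- sample(rep(c("contra", "ipsi"), n_trials_per_side))
    iti <- 4  # seconds between stimulus onsets
    onset <- 5 + (seq_len(n_stim) - 1) * iti
    dur <- max(onset) + 10
    n_frames <- ceiling(dur * fr)
    frame_times <- (seq_len(n_frames) - 1) / fr
    prefers_contra <- runif(n_boutons) < contra_frac
    kernel <- calcium_kernel(params$rise_s, params$decay_s, fr)
    onset_frame <- round(onset * fr) + 1
    soma <- matrix(0, n_boutons, n_frames)
    for (i in seq_len(n_boutons)) {
      pref_side <- if (prefers_contra[i]) "contra" else "ipsi"
      amp <- if_else(side == pref_side, base_amp + effect_size, base_amp)
      imp <- numeric(n_frames)
      imp[onset_frame] <- amp
      s <- convolve_impulses(imp, kernel)
      soma[i, ] <- params$baseline_f * (1 + s) +
        rnorm(n_frames, 0, params$noise_sd * params$baseline_f)
    }
    list(
      traces = roi_trace_set(soma, NULL, frame_times,
                             roi_labels = rep("bouton", n_boutons)),
      stim_table = tibble(onset_time_s = onset, side = side),
      ground_truth = tibble(roi = seq_len(n_boutons),
                            prefers_contra = prefers_contra)
    )
  })
}
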