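# Shared fixture builders and independent oracles.

# O(n*m) pairwise AUROC oracle.
auroc_brute <- function(pos, neg) {
  wins <- 0
  for (p in pos) {
    for (q in neg) {
      wins <- wins + (p > q) + 0.5 * (p == q)
    }
  }
  wins / (length(pos) * length(neg))
}

# Enumeration oracle for the two-sided Fisher test: table probabilities
# from binomial coefficients (independent of dhyper).
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0, k - n):min(k, m)
  prob <- vapply(support, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  obs <- prob[support == a]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# Hand-built ball trace from sample points.
make_trace <- function(time_s, angle_deg) {
  tibble::tibble(time_s = time_s, angle_deg = angle_deg)
}

# Deterministic ramp agent answering every cue correctly at a fixed RT.
correct_agent <- function(config, rt = 0.4) {
  function(cue_side, laser) {
    dir <- if (is.na(cue_side)) {
      "pos"
    } else if ((cue_side == "right") == (config$contingency == "inward")) {
      "pos"
    } else {
      "neg"
    }
    sgn <- if (dir == "pos") 1 else -1
    t <- seq(config$tick_s, config$response_window_s, by = config$tick_s)
    make_trace(t, sgn * config$threshold_deg * t / rt)
  }
}

still_agent <- function(config) {
  t <- seq(config$tick_s, max(config$response_window_s,
                              config$spontaneous_trial_s),
           by = config$tick_s)
  function(cue_side, laser) make_trace(t, rep(0, length(t)))
}

# Synthetic decoding features with a known class separation.
make_features <- function(n_trials = 40, n_rois = 20, effect = 1,
                          noise_sd = 0.3, seed = 1,
                          n_labeled = 0, labeled_gain = 1) {
  withr::with_seed(seed, {
    labels <- rep(c("contraversive", "ipsiversive"), each = n_trials / 2)
    cue <- rep(c("right", "left"), n_trials / 2)
    w <- rnorm(n_rois, 0, effect)
    roi_labels <- rep("unlabeled", n_rois)
    if (n_labeled > 0) {
      roi_labels[seq_len(n_labeled)] <- "labeled"
      w[seq_len(n_labeled)] <- w[seq_len(n_labeled)] * labeled_gain
    }
    f <- outer(ifelse(labels == "contraversive", 1, -1), w) +
      matrix(rnorm(n_trials * n_rois, 0, noise_sd), n_trials)
    structure(
      list(features = f, labels = labels, cue_side = cue,
           roi_labels = roi_labels),
      class = "decoding_features"
    )
  })
}

# Random-walk ball traces for property batteries.
random_trace <- function(n_ticks = 100, step_sd = 1.2, tick_s = 0.01) {
  make_trace(seq_len(n_ticks) * tick_s, cumsum(rnorm(n_ticks, 0, step_sd)))
}
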