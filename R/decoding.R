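#' Configuration for linear action decoding
#'
#' Parameters of the cross-validated linear support-vector-machine
#' procedure used to decode the selected action (contraversive vs
#' ipsiversive) from population activity.
#'
#' @param cost Soft-margin penalty C of the linear SVM (default 1e-4).
#' @param folds Cross-validation folds (default 10).
#' @param iterations Subsampling iterations (default 1000).
#' @param trials_per_condition Trials sampled per action label per
#'   iteration (default 5), drawn with right/left cue composition as
#'   balanced as the session allows.
#' @param window Feature window around the response, seconds (default
#'   `c(-0.2, 0.4)`).
#' @param seed Optional integer seed.
#' @return A `decoder_config` list.
#' @export
decoder_config <- function(cost = 1e-4, folds = 10, iterations = 1000,
                           trials_per_condition = 5,
                           window = c(-0.2, 0.4), seed = NULL) {
  stopifnot(cost > 0, folds >= 2, iterations >= 1,
            trials_per_condition >= 2)
  structure(
    list(cost = cost, folds = folds, iterations = iterations,
         trials_per_condition = trials_per_condition, window = window,
         seed = seed),
    class = "decoder_config"
  )
}

#' Extract response-aligned decoding features
#'
#' Averages each ROI's activity over the response window (default -0.2 s
#' to +0.4 s around the response) to one scalar per ROI per trial.
#'
#' @param tensor A response-aligned `trial_tensor`.
#' @param window Averaging window (defaults to the tensor's window).
#' @return A `decoding_features` list: `features` (trials x ROIs matrix),
#'   `labels` (`"contraversive"`/`"ipsiversive"` per trial), `cue_side`,
#'   `roi_labels`.
#' @export
response_features <- function(tensor, window = NULL) {
  stopifnot(inherits(tensor, "trial_tensor"), tensor$anchor == "response")
  window <- window %||% tensor$window
  cols <- which(tensor$rel_time_s >= window[1] &
                  tensor$rel_time_s <= window[2])
  if (length(cols) == 0) {
    stop_bad_arg("feature window contains no frames")
  }
  feats <- t(apply(tensor$activity[, , cols, drop = FALSE], c(1, 2), mean))
  structure(
    list(features = feats, labels = tensor$trials$action,
         cue_side = tensor$trials$cue_side,
         roi_labels = tensor$roi_labels),
    class = "decoding_features"
  )
}

# Sample `k` trials of one action label with cue composition as balanced
# as available; NULL when the label is absent.
sample_balanced <- function(idx_by_cue, k) {
  available <- lengths(idx_by_cue)
  if (sum(available) < k || sum(available > 0) == 0) {
    return(NULL)
  }
  target <- c(floor(k / 2), ceiling(k / 2))
  if (runif(1) < 0.5) target <- rev(target)
  take <- pmin(target, available)
  deficit <- k - sum(take)
  if (deficit > 0) {
    spare <- available - take
    for (j in order(spare, decreasing = TRUE)) {
      add <- min(deficit, spare[j])
      take[j] <- take[j] + add
      deficit <- deficit - add
      if (deficit == 0) break
    }
  }
  if (deficit > 0) {
    return(NULL)
  }
  unlist(map2(idx_by_cue, take, function(idx, tk) {
    if (tk == 0) integer(0) else idx[sample.int(length(idx), tk)]
  }), use.names = FALSE)
}

# Draw a balanced subsample for one session: k trials per action label.
subsample_session <- function(fs, k, session_name = "session") {
  out <- lapply(c("contraversive", "ipsiversive"), function(lbl) {
    idx <- which(fs$labels == lbl)
    if (length(idx) == 0) {
      stop_bad_arg(paste0(session_name, " lacks ", lbl, " trials"))
    }
    by_cue <- split(idx, fs$cue_side[idx])
    if (length(by_cue) == 1) {
      by_cue <- c(by_cue, list(integer(0)))
    }
    picked <- sample_balanced(by_cue, k)
    if (is.null(picked)) {
      stop_bad_arg(paste0(session_name, " has fewer than ", k, " ", lbl,
                          " trials"))
    }
    picked
  })
  names(out) <- c("contraversive", "ipsiversive")
  out
}

# Stratified fold assignment: deal shuffled within-class indices to folds.
make_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (lbl in unique(labels)) {
    idx <- which(labels == lbl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# One cross-validated accuracy (and its shuffled-test-label counterpart)
# for a feature matrix and binary labels.
cv_accuracy <- function(x, y, cost, n_folds) {
  y <- factor(y)
  n_folds <- min(n_folds, length(y))
  fold <- make_folds(y, n_folds)
  correct <- 0
  correct_shuf <- 0
  total <- 0
  for (f in seq_len(n_folds)) {
    test <- fold == f
    if (!any(test) || length(unique(y[!test])) < 2) next
    fit <- e1071::svm(x[!test, , drop = FALSE], y[!test],
                      kernel = "linear", cost = cost, scale = FALSE)
    pred <- predict(fit, x[test, , drop = FALSE])
    correct <- correct + sum(pred == y[test])
    y_shuf <- y[test][sample.int(sum(test))]
    correct_shuf <- correct_shuf + sum(pred == y_shuf)
    total <- total + sum(test)
  }
  c(accuracy = correct / total, shuffled = correct_shuf / total)
}

new_decoding_result <- function(acc, null_acc, config, n_rois, n_sessions) {
  null_int <- quantile(null_acc, c(0.025, 0.975), names = FALSE)
  m <- mean(acc)
  structure(
    list(
      mean_accuracy = m,
      sd_across_iterations = sd(acc),
      null_mean = mean(null_acc),
      null_central_interval = null_int,
      significant = m < null_int[1] || m > null_int[2],
      iteration_accuracies = acc,
      null_accuracies = null_acc,
      config = config,
      n_rois = n_rois,
      n_sessions = n_sessions
    ),
    class = "decoding_result"
  )
}

#' Decode actions from pseudotrials combined across sessions
#'
#' Trains linear SVM classifiers to predict the selected action from
#' population activity pooled across separately recorded sessions. Per
#' iteration: each session contributes `trials_per_condition` randomly
#' subsampled trials per action label (cue-balanced); same-label trials
#' are randomly paired across sessions into pseudotrials whose feature
#' vector concatenates all sessions' ROIs; classifier accuracy is
#' estimated by stratified k-fold cross-validation and averaged across
#' folds. The final accuracy is the mean across iterations. Chance is
#' estimated by an identical procedure with shuffled test-set labels;
#' the observed mean is significant when outside the central 95% of the
#' shuffled iteration means. A single session degenerates to
#' within-session decoding with the identical pipeline.
#'
#' @param sessions A list of `decoding_features` (one per session).
#' @param config A [decoder_config()].
#' @return A `decoding_result`.
#' @export
decode_pseudotrials <- function(sessions, config = decoder_config()) {
  if (inherits(sessions, "decoding_features")) {
    sessions <- list(sessions)
  }
  stopifnot(length(sessions) >= 1)
  k <- config$trials_per_condition
  with_seed(config$seed, {
    acc <- null_acc <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      parts <- imap(sessions, function(fs, si) {
        name <- paste0("session ", si)
        picks <- subsample_session(fs, k, name)
        # random pairing order across sessions within each label
        lapply(picks, function(idx) {
          fs$features[idx[sample.int(k)], , drop = FALSE]
        })
      })
      x <- rbind(
        do.call(cbind, lapply(parts, `[[`, "contraversive")),
        do.call(cbind, lapply(parts, `[[`, "ipsiversive"))
      )
      y <- rep(c("contraversive", "ipsiversive"), each = k)
      res <- cv_accuracy(x, y, config$cost, config$folds)
      acc[it] <- res["accuracy"]
      null_acc[it] <- res["shuffled"]
    }
    new_decoding_result(acc, null_acc, config,
                        n_rois = sum(vapply(sessions,
                                            function(s) ncol(s$features),
                                            numeric(1))),
                        n_sessions = length(sessions))
  })
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "Action decoding: accuracy %.3f +/- %.3f (sd over %d iterations)\n",
    x$mean_accuracy, x$sd_across_iterations, length(x$iteration_accuracies)))
  cat(sprintf("  chance (shuffled test labels): %.3f, central 95%% [%.3f, %.3f] -> %s\n",
              x$null_mean, x$null_central_interval[1],
              x$null_central_interval[2],
              if (x$significant) "SIGNIFICANT" else "n.s."))
  invisible(x)
}

#' @export
tidy.decoding_result <- function(x, ...) {
  tibble(
    mean_accuracy = x$mean_accuracy,
    sd_across_iterations = x$sd_across_iterations,
    null_mean = x$null_mean,
    null_lo = x$null_central_interval[1],
    null_hi = x$null_central_interval[2],
    significant = x$significant
  )
}

#' @export
glance.decoding_result <- function(x, ...) {
  tidy(x)
}

#' Compare decoding by labeled versus matched unlabeled neurons
#'
#' For each session containing both projection-labeled and unlabeled
#' ROIs, runs the within-session decoding procedure separately on the
#' labeled population and on a random subsample of unlabeled ROIs matched
#' to the labeled count (re-drawn every iteration), and averages each
#' population's cross-validated accuracy over iterations. Session-wise
#' accuracies for the two populations are compared with a paired
#' signed-rank test.
#'
#' @param sessions A list of `decoding_features`, each with `roi_labels`
#'   containing `"labeled"` and `"unlabeled"` entries.
#' @param config A [decoder_config()].
#' @return A `labeled_decoding_comparison`: `per_session` tibble
#'   (`accuracy_labeled`, `accuracy_unlabeled`), `n_labeled_wins`, and the
#'   paired rank-test result.
#' @export
decode_within_session <- function(sessions, config = decoder_config()) {
  if (inherits(sessions, "decoding_features")) {
    sessions <- list(sessions)
  }
  k <- config$trials_per_condition
  rows <- with_seed(config$seed, {
    imap(sessions, function(fs, si) {
      lab_idx <- which(fs$roi_labels == "labeled")
      unlab_idx <- which(fs$roi_labels == "unlabeled")
      if (length(lab_idx) == 0) {
        stop_bad_arg(paste0("session ", si, " has no labeled ROIs"))
      }
      if (length(unlab_idx) < length(lab_idx)) {
        stop_bad_arg(paste0("session ", si,
                            " has fewer unlabeled than labeled ROIs"))
      }
      acc_lab <- acc_unlab <- numeric(config$iterations)
      for (it in seq_len(config$iterations)) {
        picks <- subsample_session(fs, k, paste0("session ", si))
        idx <- c(picks$contraversive, picks$ipsiversive)
        y <- rep(c("contraversive", "ipsiversive"), each = k)
        sub <- if (length(unlab_idx) == length(lab_idx)) {
          unlab_idx
        } else {
          unlab_idx[sample.int(length(unlab_idx), length(lab_idx))]
        }
        acc_lab[it] <- cv_accuracy(
          fs$features[idx, lab_idx, drop = FALSE], y,
          config$cost, config$folds)["accuracy"]
        acc_unlab[it] <- cv_accuracy(
          fs$features[idx, sub, drop = FALSE], y,
          config$cost, config$folds)["accuracy"]
      }
      tibble(session = si, n_labeled = length(lab_idx),
             accuracy_labeled = mean(acc_lab),
             accuracy_unlabeled = mean(acc_unlab))
    })
  })
  per_session <- list_rbind(rows)
  test <- if (nrow(per_session) >= 2) {
    tryCatch(rank_tests(per_session$accuracy_labeled,
                        per_session$accuracy_unlabeled, paired = TRUE),
             orientrack_error = function(e) tibble(p = NA_real_,
                                                   z = NA_real_))
  } else {
    tibble(p = NA_real_, z = NA_real_)
  }
  structure(
    list(
      per_session = per_session,
      n_labeled_wins = sum(per_session$accuracy_labeled >
                             per_session$accuracy_unlabeled),
      n_sessions = nrow(per_session),
      rank_test = test
    ),
    class = "labeled_decoding_comparison"
  )
}

#' @export
print.labeled_decoding_comparison <- function(x, ...) {
  cat(sprintf(
    "Labeled vs unlabeled decoding: labeled higher in %d/%d sessions (signed-rank p = %.3g)\n",
    x$n_labeled_wins, x$n_sessions, x$rank_test$p))
  print(x$per_session)
  invisible(x)
}

#' @export
tidy.labeled_decoding_comparison <- function(x, ...) {
  x$per_session
}
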