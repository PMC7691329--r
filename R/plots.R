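# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline
#'   geom_col geom_errorbar geom_point geom_line geom_abline labs
#'   facet_wrap position_dodge theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Null distribution of a permutation test
#'
#' Histogram of the permutation null with the observed effect marked.
#'
#' @param object A `perm_test`.
#' @param ... Ignored.
#' @export
autoplot.perm_test <- function(object, ...) {
  ggplot(tibble(null = object$null_samples), aes(x = .data$null)) +
    geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$observed_effect, colour = "firebrick",
               linewidth = 1) +
    labs(
      x = "laser-induced change (permutation null)", y = "count",
      title = sprintf("Observed effect %.3f, two-tailed p = %.3g",
                      object$observed_effect, object$p_two_sided)
    ) +
    theme_minimal()
}

#' Shuffle-null interval for a preference score
#'
#' @param object A `shuffle_null`.
#' @param ... Ignored.
#' @export
autoplot.shuffle_null <- function(object, ...) {
  ggplot(tibble(null = object$null_samples), aes(x = .data$null)) +
    geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$observed, colour = "firebrick",
               linewidth = 1) +
    geom_vline(xintercept = c(object$null_lo, object$null_hi),
               linetype = "dashed") +
    labs(x = "score (shuffled labels)", y = "count",
         title = if (object$significant) "outside the central interval" else
           "within the central interval") +
    theme_minimal()
}

#' Decoding accuracy against its shuffled-label chance distribution
#'
#' @param object A `decoding_result`.
#' @param ... Ignored.
#' @export
autoplot.decoding_result <- function(object, ...) {
  ggplot(tibble(null = object$null_accuracies), aes(x = .data$null)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$mean_accuracy, colour = "firebrick",
               linewidth = 1) +
    labs(x = "accuracy (shuffled test labels)", y = "iterations",
         title = sprintf("Mean accuracy %.3f +/- %.3f",
                         object$mean_accuracy,
                         object$sd_across_iterations)) +
    theme_minimal()
}

#' Per-cue performance under laser and non-laser conditions
#'
#' Dodged bars of the incorrect and timeout rates per cue side and laser
#' condition from a [performance_summary()] table.
#'
#' @param perf A [performance_summary()] tibble.
#' @export
plot_performance <- function(perf) {
  long <- tidyr::pivot_longer(
    perf, c("incorrect_rate", "timeout_rate"),
    names_to = "measure", values_to = "rate"
  )
  ggplot(long, aes(x = .data$cue_side, y = .data$rate,
                   fill = .data$laser)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    facet_wrap(~measure) +
    labs(x = "cue side", y = "rate", fill = "laser") +
    theme_minimal()
}

#' Fractions of preferring boutons with exact binomial error bars
#'
#' @param population A tibble with columns `group`, `k`, `n` (preferring
#'   count and total per population).
#' @export
plot_preference_fractions <- function(population) {
  ci <- binomial_ci(population$k, population$n)
  df <- dplyr::bind_cols(population, ci)
  ggplot(df, aes(x = .data$group, y = .data$estimate)) +
    geom_col(fill = "grey70", colour = "grey40", width = 0.6) +
    geom_errorbar(aes(ymin = .data$lo, ymax = .data$hi), width = 0.15) +
    labs(x = NULL, y = "fraction preferring") +
    theme_minimal()
}
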