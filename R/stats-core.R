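#' Two-sided Fisher's exact test in log space
#'
#' Computes the two-sided p-value of independence for a 2x2 contingency table
#' using the point-probability rule: the p-value is the sum of the
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table. The sum is
#' accumulated in log space, so astronomically small p-values (for example
#' comparisons of strongly contra- versus ipsi-preferring bouton populations,
#' where p falls well below 1e-300) remain representable.
#'
#' @param table A 2x2 matrix of non-negative integer counts, rows =
#'   populations, columns = preference classes. Alternatively a length-4
#'   vector `c(a, b, c, d)` filling the table by row.
#' @return A tibble with columns `log10_p` (base-10 log of the two-sided
#'   p-value, always <= 0) and `p` (the p-value itself; 0 when below the
#'   smallest representable double).
#' @examples
#' fisher_exact_two_sided(matrix(c(233, 35, 48, 261), 2, byrow = TRUE))
#' @export
fisher_exact_two_sided <- function(table) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2, 2)))
    counts <- as.vector(t(table))
  } else {
    stopifnot(length(table) == 4)
    counts <- as.numeric(table)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_bad_arg("counts must be non-negative integers")
  }
  if (sum(counts) == 0) {
    stop_bad_arg("empty table")
  }
  a <- counts[1]; b <- counts[2]; c_ <- counts[3]; d <- counts[4]
  m <- a + b      # row 1 total
  n <- c_ + d     # row 2 total
  k <- a + c_     # column 1 total
  support <- max(0, k - n):min(k, m)
  log_dens <- dhyper(support, m, n, k, log = TRUE)
  log_obs <- dhyper(a, m, n, k, log = TRUE)
  # relative tolerance on the point probability, as in standard practice,
  # guards against ties lost to floating-point rounding
  keep <- log_dens <= log_obs + log1p(1e-7)
  log_p <- min(logsumexp(log_dens[keep]), 0)
  tibble(log10_p = log_p / log(10), p = exp(log_p))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Inverts the two binomial tails at `(1 - level)/2` each; the standard
#' interval behind error bars on proportions of preferring boutons or of
#' significantly tuned neurons.
#'
#' @param successes,n Integer counts, `0 <= successes <= n`, `n > 0`.
#' @param level Confidence level (default 0.95).
#' @return A tibble with `estimate`, `lo`, `hi`.
#' @export
binomial_ci <- function(successes, n, level = 0.95) {
  stopifnot(length(successes) == length(n))
  if (any(n <= 0)) {
    stop_bad_arg("n must be positive")
  }
  if (any(successes < 0 | successes > n)) {
    stop_bad_arg("successes must lie in [0, n]")
  }
  alpha <- (1 - level) / 2
  lo <- ifelse(successes == 0, 0, qbeta(alpha, successes, n - successes + 1))
  hi <- ifelse(successes == n, 1, qbeta(1 - alpha, successes + 1, n - successes))
  tibble(estimate = successes / n, lo = lo, hi = hi)
}

#' Area under the ROC curve from two samples
#'
#' Rank-statistic definition: the fraction of (positive, negative) pairs in
#' which the positive value exceeds the negative one, ties counting 1/2.
#' Used to score a neuron's or bouton's discrimination between two trial
#' conditions (positive class = contraversive/contralateral by convention).
#'
#' @param positives,negatives Non-empty numeric vectors of per-trial
#'   responses for the two conditions.
#' @return A single number in \[0, 1\].
#' @export
auroc <- function(positives, negatives) {
  positives <- positives[!is.na(positives)]
  negatives <- negatives[!is.na(negatives)]
  if (length(positives) == 0 || length(negatives) == 0) {
    stop_bad_arg("both groups must be non-empty")
  }
  n_pos <- length(positives)
  n_neg <- length(negatives)
  r <- rank(c(positives, negatives))
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Preference score from an AUROC value
#'
#' Maps AUROC in \[0, 1\] to \[-1, 1\]: `2 * (auroc - 0.5)`. +1 means
#' complete preference for the positive (contra) class, -1 complete
#' preference for the other.
#'
#' @param auroc AUROC value(s) in \[0, 1\].
#' @export
preference_score <- function(auroc) {
  2 * (auroc - 0.5)
}

#' Bonferroni-adjusted per-comparison significance level
#'
#' For a family of `n_comparisons` tests controlled at `alpha`, each
#' comparison is evaluated at `alpha / n_comparisons`; the default is the
#' two-cue family (right and left cue trials) at 0.05, giving 0.025.
#'
#' @param alpha Family-wise level (default 0.05).
#' @param n_comparisons Number of comparisons in the family (default 2).
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_comparisons = 2) {
  stopifnot(alpha > 0, alpha < 1, n_comparisons >= 1)
  alpha / n_comparisons
}

#' Shuffle-null significance of a two-group score
#'
#' Builds an empirical null for a score comparing two groups of values by
#' pooling the values, randomly re-partitioning them into groups of the
#' original sizes, and recomputing the score. The observed score is called
#' significant when it falls outside the central `central` interval of the
#' shuffled distribution (for `central = 0.95`, outside the 2.5th-97.5th
#' percentiles; a two-sided test at alpha = 0.05).
#'
#' @param values_a,values_b Numeric vectors for the two groups.
#' @param score_fn Function of two numeric vectors returning a scalar score.
#' @param n_shuffles Number of random re-partitions (default 1000).
#' @param central Width of the central null interval (default 0.95).
#' @param seed Optional integer seed; fixed seed gives identical results.
#' @return An object of class `shuffle_null` with fields `observed`,
#'   `null_lo`, `null_hi`, `significant`, `n_shuffles`, `null_samples`.
#' @export
shuffle_significance <- function(values_a, values_b, score_fn,
                                 n_shuffles = 1000, central = 0.95,
                                 seed = NULL) {
  stopifnot(n_shuffles >= 1, central > 0, central < 1)
  observed <- score_fn(values_a, values_b)
  pooled <- c(values_a, values_b)
  n_a <- length(values_a)
  n_tot <- length(pooled)
  null_samples <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      idx <- sample.int(n_tot, n_a)
      score_fn(pooled[idx], pooled[-idx])
    }, numeric(1))
  })
  tail <- (1 - central) / 2
  bounds <- quantile(null_samples, c(tail, 1 - tail), names = FALSE)
  structure(
    list(
      observed = observed,
      null_lo = bounds[1],
      null_hi = bounds[2],
      significant = observed < bounds[1] || observed > bounds[2],
      n_shuffles = n_shuffles,
      central = central,
      null_samples = null_samples
    ),
    class = "shuffle_null"
  )
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat("Shuffle-null test (", x$n_shuffles, " shuffles)\n", sep = "")
  cat(sprintf("  observed: %.4f  null central %.0f%%: [%.4f, %.4f]  %s\n",
              x$observed, 100 * x$central, x$null_lo, x$null_hi,
              if (x$significant) "SIGNIFICANT" else "n.s."))
  invisible(x)
}

#' @export
tidy.shuffle_null <- function(x, ...) {
  tibble(
    observed = x$observed, null_lo = x$null_lo, null_hi = x$null_hi,
    significant = x$significant, n_shuffles = x$n_shuffles
  )
}

#' Animal-wise permutation test of a laser effect
#'
#' Tests whether a laser-induced change in a pooled behavioral metric could
#' arise by chance, against the null that the metric does not depend on the
#' laser. Each permutation round re-assigns the laser labels at random
#' across trials independently within each animal (preserving every
#' animal's laser-trial count), then pools all animals' trials and
#' recomputes the metric. The two-tailed p-value is the proportion of null
#' values at least as extreme as the observed one on either side of a null
#' centered at zero, i.e. `mean(|null| >= |observed|)`; no +1 smoothing is
#' applied, so the resolution is `1/n_perm` (reported alongside).
#'
#' @param per_animal_trials A list of per-animal trial tibbles, each with a
#'   logical `laser` column plus whatever columns `metric_fn` needs.
#' @param metric_fn Function taking the pooled trial tibble and returning a
#'   scalar laser-induced change (typically laser minus non-laser).
#' @param n_perm Number of permutation rounds (default 1000).
#' @param seed Optional integer seed.
#' @return An object of class `perm_test`: `observed_effect`,
#'   `null_samples`, `p_two_sided`, `n_permutations`, `resolution`, `seed`.
#' @export
permutation_test_laser <- function(per_animal_trials, metric_fn,
                                   n_perm = 1000, seed = NULL) {
  stopifnot(is.list(per_animal_trials), length(per_animal_trials) >= 1,
            n_perm >= 1)
  for (tr in per_animal_trials) {
    if (!"laser" %in% names(tr)) {
      stop_bad_arg("each animal's trial table needs a `laser` column")
    }
    n_laser <- sum(tr$laser)
    if (n_laser == 0 || n_laser == nrow(tr)) {
      stop_bad_arg("each animal needs both laser and non-laser trials")
    }
  }
  pooled <- bind_rows(per_animal_trials)
  observed <- metric_fn(pooled)
  sizes <- vapply(per_animal_trials, nrow, integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  laser_col <- pooled$laser
  null_samples <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      shuffled <- laser_col
      for (j in seq_along(sizes)) {
        idx <- offsets[j] + seq_len(sizes[j])
        shuffled[idx] <- laser_col[idx][sample.int(sizes[j])]
      }
      pooled$laser <- shuffled
      metric_fn(pooled)
    }, numeric(1))
  })
  structure(
    list(
      observed_effect = observed,
      null_samples = null_samples,
      p_two_sided = mean(abs(null_samples) >= abs(observed)),
      n_permutations = n_perm,
      resolution = 1 / n_perm,
      seed = seed
    ),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Animal-wise laser permutation test\n")
  cat(sprintf("  observed effect: %.4f\n", x$observed_effect))
  cat(sprintf("  two-tailed p: %.4g (resolution %.4g, %d permutations)\n",
              x$p_two_sided, x$resolution, x$n_permutations))
  invisible(x)
}

#' @export
tidy.perm_test <- function(x, ...) {
  tibble(
    observed_effect = x$observed_effect,
    p_two_sided = x$p_two_sided,
    n_permutations = x$n_permutations,
    resolution = x$resolution
  )
}

#' @export
glance.perm_test <- function(x, ...) {
  tidy(x)
}

#' Wilcoxon rank tests with a normal-approximation z
#'
#' Paired mode runs the signed-rank test with zero differences dropped
#' (classical convention); unpaired mode runs the rank-sum test. The
#' p-value comes from [stats::wilcox.test()] (exact for small tie-free
#' samples, normal approximation otherwise); the z statistic is the
#' tie-corrected normal approximation, signed so that positive z means `x`
#' tends to exceed `y`.
#'
#' @param x,y Numeric vectors; equal length when `paired = TRUE`.
#' @param paired Signed-rank (`TRUE`) or rank-sum (`FALSE`).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return A tibble with `p`, `z`, `statistic`, `n_used`, `method`.
#' @export
rank_tests <- function(x, y, paired = FALSE, alternative = "two.sided") {
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (paired) {
    if (length(x) != length(y)) {
      stop_bad_arg("paired test needs equal-length vectors")
    }
    keep <- !is.na(x) & !is.na(y)
    d <- x[keep] - y[keep]
    d <- d[d != 0]
    n <- length(d)
    if (n < 2) {
      stop_bad_arg("fewer than 2 usable (non-zero) paired differences")
    }
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- suppressWarnings(
      wilcox.test(x[keep], y[keep], paired = TRUE,
                  alternative = alternative, exact = NULL)$p.value
    )
    tibble(p = p, z = z, statistic = v, n_used = n,
           method = "signed-rank")
  } else {
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    n1 <- length(x)
    n2 <- length(y)
    if (n1 < 1 || n2 < 1 || n1 + n2 < 3) {
      stop_bad_arg("too few observations for the rank-sum test")
    }
    r <- rank(c(x, y))
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    n_tot <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((n_tot + 1) - sum(ties^3 - ties) / (n_tot * (n_tot - 1)))
    z <- (u - mu) / sqrt(sigma2)
    p <- suppressWarnings(
      wilcox.test(x, y, alternative = alternative, exact = NULL)$p.value
    )
    tibble(p = p, z = z, statistic = u, n_used = n_tot,
           method = "rank-sum")
  }
}

#' Normalize back-labeled cell counts along the anteroposterior axis
#'
#' Bins cell positions (e.g. retrogradely labeled projection neurons) along
#' the AP axis and divides per-bin counts by the total number of cells
#' falling inside a normalization range (e.g. the full extent of the frontal
#' cortex), so bins report proportions of that reference population. Cells
#' outside the normalization range never enter the denominator.
#'
#' @param cells A data frame with a numeric `ap_mm` column; any grouping
#'   columns named in `by` (e.g. a tracer color tag) are normalized
#'   separately.
#' @param bin_width Bin width in mm (default 0.5).
#' @param normalization_range Length-2 numeric `(lo, hi)` AP range whose
#'   cell count forms the denominator.
#' @param by Optional character vector of grouping columns.
#' @return A tibble with `bin_lo`, `bin_mid`, `n`, `proportion` (plus the
#'   `by` columns). Proportions within the range sum to <= 1 per group.
#' @export
normalized_cell_counts <- function(cells, bin_width = 0.5,
                                   normalization_range, by = NULL) {
  stopifnot(is.data.frame(cells), "ap_mm" %in% names(cells))
  if (any(!is.finite(cells$ap_mm))) {
    stop_bad_arg("all AP positions must be finite")
  }
  stopifnot(length(normalization_range) == 2,
            normalization_range[1] < normalization_range[2])
  lo <- normalization_range[1]
  hi <- normalization_range[2]
  cells <- as_tibble(cells)
  cells$bin_lo <- floor(cells$ap_mm / bin_width) * bin_width
  grouped <- if (is.null(by)) {
    group_by(cells, .data$bin_lo)
  } else {
    group_by(cells, across(dplyr::all_of(c(by, "bin_lo"))))
  }
  binned <- summarise(grouped, n = dplyr::n(), .groups = "drop_last")
  denom_of <- function(df) {
    sum(df$n[df$bin_lo >= lo & df$bin_lo + bin_width <= hi])
  }
  binned <- if (is.null(by)) {
    d <- denom_of(binned)
    if (d == 0) stop_bad_arg("no cells in the normalization range")
    mutate(ungroup(binned), proportion = .data$n / d)
  } else {
    out <- mutate(binned, proportion = {
      d <- denom_of(dplyr::pick(dplyr::everything()))
      if (d == 0) stop_bad_arg("no cells in the normalization range")
      .data$n / d
    })
    ungroup(out)
  }
  mutate(arrange(binned, .data$bin_lo),
         bin_mid = .data$bin_lo + bin_width / 2,
         .after = "bin_lo")
}
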