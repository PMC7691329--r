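test_that("log-space Fisher test matches enumeration and stats::fisher.test", {
  # frozen small-table values
  expect_equal(fisher_exact_two_sided(c(1, 1, 1, 1))$p, 1, tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(c(5, 0, 0, 5))$p, 2 / 252,
               tolerance = 1e-12)
  # enumeration oracle across random tables with total <= 40
  withr::with_seed(7, {
    for (i in 1:60) {
      tot <- sample(4:40, 1)
      a <- sample(0:tot, 1)
      b <- sample(0:(tot - a), 1)
      c_ <- sample(0:(tot - a - b), 1)
      d <- tot - a - b - c_
      if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) next
      ours <- fisher_exact_two_sided(c(a, b, c_, d))
      oracle <- fisher_enum_oracle(a, b, c_, d)
      expect_equal(exp(ours$log10_p * log(10)), oracle,
                   tolerance = 1e-10)
      ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
      expect_equal(ours$p, min(ft, 1), tolerance = 1e-7)
    }
  })
})

test_that("Fisher test stays finite in log space for extreme tables", {
  res <- fisher_exact_two_sided(c(2000, 0, 0, 2000))
  expect_true(is.finite(res$log10_p))
  expect_lt(res$log10_p, -300)
  expect_error(fisher_exact_two_sided(c(0, 0, 0, 0)), "empty")
})

test_that("binomial CI is the exact Clopper-Pearson interval", {
  ci <- binomial_ci(5, 10)
  bt <- binom.test(5, 10)$conf.int
  expect_equal(c(ci$lo, ci$hi), as.numeric(bt), tolerance = 1e-10)
  expect_equal(binomial_ci(0, 10)$lo, 0)
  expect_equal(binomial_ci(10, 10)$hi, 1)
  withr::with_seed(3, {
    for (i in 1:20) {
      n <- sample(1:200, 1)
      k <- sample(0:n, 1)
      ci <- binomial_ci(k, n)
      bt <- binom.test(k, n)$conf.int
      expect_equal(c(ci$lo, ci$hi), as.numeric(bt), tolerance = 1e-10)
      expect_true(ci$lo <= k / n && k / n <= ci$hi)
    }
  })
  expect_error(binomial_ci(1, 0))
})

test_that("AUROC equals the pairwise brute-force oracle and is antisymmetric", {
  expect_equal(auroc(c(10, 20), c(1, 2)), 1)
  expect_equal(auroc(rep(3, 4), rep(3, 5)), 0.5)
  expect_equal(auroc(c(1, 3), 2), 0.5)
  withr::with_seed(11, {
    for (i in 1:40) {
      n1 <- sample(1:8, 1)
      n2 <- sample(1:8, 1)
      pos <- sample(1:5, n1, replace = TRUE) + sample(c(0, 0.5), n1, TRUE)
      neg <- sample(1:5, n2, replace = TRUE) + sample(c(0, 0.5), n2, TRUE)
      expect_identical(auroc(pos, neg), auroc_brute(pos, neg))
      expect_equal(auroc(pos, neg) + auroc(neg, pos), 1)
    }
  })
  expect_error(auroc(numeric(0), 1), "non-empty")
})

test_that("shuffle-null significance behaves under null, separation, and seeds", {
  score <- function(a, b) preference_score(auroc(a, b))
  same <- rnorm(20)
  res_null <- shuffle_significance(same, same, score, n_shuffles = 300,
                                   seed = 5)
  expect_false(res_null$significant)
  sep <- shuffle_significance(rnorm(8, 10), rnorm(8, 0), score,
                              n_shuffles = 1000, seed = 5)
  expect_true(sep$significant)
  expect_equal(sep$observed, 1)
  # determinism
  r1 <- shuffle_significance(1:10, 11:20, score, n_shuffles = 50, seed = 4)
  r2 <- shuffle_significance(1:10, 11:20, score, n_shuffles = 50, seed = 4)
  expect_identical(r1$null_samples, r2$null_samples)
})

test_that("rank-based shuffle scores are invariant to monotone transforms", {
  withr::with_seed(21, {
    a <- rnorm(12)
    b <- rnorm(12, 0.8)
  })
  score <- function(x, y) auroc(x, y)
  r_raw <- shuffle_significance(a, b, score, n_shuffles = 200, seed = 2)
  r_exp <- shuffle_significance(exp(a), exp(b), score, n_shuffles = 200,
                                seed = 2)
  expect_identical(r_raw$observed, r_exp$observed)
  expect_identical(r_raw$null_samples, r_exp$null_samples)
  expect_identical(r_raw$significant, r_exp$significant)
})

test_that("permutation test returns p = 1 for label-invariant metrics and validates input", {
  trials <- list(
    tibble::tibble(laser = rep(c(TRUE, FALSE), 10), y = rnorm(20)),
    tibble::tibble(laser = rep(c(TRUE, FALSE), 15), y = rnorm(30))
  )
  res <- permutation_test_laser(trials, function(tr) 42, n_perm = 50,
                                seed = 1)
  expect_equal(res$p_two_sided, 1)
  expect_equal(res$resolution, 1 / 50)
  expect_length(res$null_samples, 50)
  bad <- list(tibble::tibble(laser = rep(TRUE, 5), y = rnorm(5)))
  expect_error(permutation_test_laser(bad, function(tr) 0),
               "laser and non-laser")
})

test_that("permutation test detects an injected laser effect", {
  metric <- function(tr) mean(tr$y[tr$laser]) - mean(tr$y[!tr$laser])
  withr::with_seed(31, {
    trials <- lapply(1:6, function(i) {
      laser <- orientrack::laser_schedule(300, 0.3)
      tibble::tibble(laser = laser, y = rnorm(300) + 0.3 * laser)
    })
  })
  res <- permutation_test_laser(trials, metric, n_perm = 400, seed = 8)
  expect_lt(res$p_two_sided, 0.025)
  expect_gt(res$observed_effect, 0.2)
})

test_that("rank tests match frozen exact enumeration and symmetry", {
  res <- rank_tests(c(1, 2, 3), c(4, 5, 6))
  # most extreme assignment of ranks: 2 of the 20 equally likely rank
  # splits are at least this extreme
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  expect_lt(res$z, 0)
  # antisymmetric swap flips z, preserves p
  x <- c(1.2, 3.1, 0.5, 2.2, 4.4, 1.9)
  y <- c(2.0, 1.1, 0.9, 3.5, 2.8, 0.3)
  a <- rank_tests(x, y, paired = TRUE)
  b <- rank_tests(y, x, paired = TRUE)
  expect_equal(a$p, b$p)
  expect_equal(a$z, -b$z)
  expect_error(rank_tests(1:4, 1:4, paired = TRUE), "usable")
  expect_error(rank_tests(1:3, 1:4, paired = TRUE), "equal-length")
})

test_that("cell-count normalization divides by the in-range total only", {
  cells <- tibble::tibble(ap_mm = c(rep(0.1, 4), rep(0.6, 6)))
  res <- normalized_cell_counts(cells, 0.5, c(0, 1))
  expect_equal(res$proportion, c(0.4, 0.6))
  expect_equal(sum(res$proportion), 1)
  # distractor cells outside the range change nothing
  with_distractors <- dplyr::bind_rows(cells,
                                       tibble::tibble(ap_mm = rep(3.3, 50)))
  res2 <- normalized_cell_counts(with_distractors, 0.5, c(0, 1))
  expect_equal(res2$proportion[res2$bin_lo < 1], res$proportion)
  expect_error(normalized_cell_counts(tibble::tibble(ap_mm = 5), 0.5,
                                      c(0, 1)), "normalization range")
})

test_that("Bonferroni helper gives the two-cue per-comparison level", {
  expect_equal(bonferroni_alpha(), 0.025)
  expect_equal(bonferroni_alpha(0.05, 5), 0.01)
})
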