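test_that("exhaustive oracle enumerates all splits with strict ordering", {
  ex <- permutation_test_exhaustive(c(1, 2), c(1, 2))
  expect_equal(ex$n_resamples, choose(4, 2))
  # frozen from hand enumeration: pool {5,6,1,2}, v0 = 4 is the max split
  ex2 <- permutation_test_exhaustive(c(5, 6), c(1, 2))
  expect_equal(ex2$p_value, 0)
  # frozen from enumerating C(6,3)=20 splits of {3,4,5,3,4,5}: 6 splits
  # have a mean difference strictly above v0 = 0
  ex3 <- permutation_test_exhaustive(c(3, 4, 5), c(3, 4, 5))
  expect_equal(ex3$p_value, 6 / 20)
  expect_error(permutation_test_exhaustive(rnorm(15), rnorm(15)), "bound")
})

test_that("Monte-Carlo permutation agrees with the exhaustive oracle", {
  set.seed(14)
  for (case in 1:5) {
    nA <- sample(3:6, 1); nB <- sample(3:6, 1)
    a <- round(rnorm(nA), 1); b <- round(rnorm(nB, 0.5), 1)
    ex <- permutation_test_exhaustive(a, b)
    mc <- permutation_test_independent(a, b, n_resamples = 10000,
                                       seed = 100 + case)
    expect_lt(abs(mc$p_value - ex$p_value), 0.02)
  }
  # symmetric samples: p near the oracle's centre value
  mc <- permutation_test_independent(c(3, 4, 5), c(3, 4, 5), seed = 1)
  expect_gt(mc$p_value, 0.25)
  expect_lt(mc$p_value, 0.7)
})

test_that("permutation engine contract: sizes, tail rule, determinism", {
  r <- permutation_test_independent(c(10, 11, 12), c(1, 2, 3),
                                    n_resamples = 2000, seed = 3)
  expect_equal(r$p_value, 0)          # v0 is the maximum achievable split
  expect_length(r$null_values, 2000)
  expect_false(is.unsorted(r$null_values))
  r2 <- permutation_test_independent(c(10, 11, 12), c(1, 2, 3),
                                     n_resamples = 2000, seed = 3)
  expect_identical(r$null_values, r2$null_values)
  expect_error(permutation_test_independent(numeric(0), 1:3), "non-empty")
  # optional conservative floor instead of exact zero
  rf <- permutation_test_independent(c(10, 11, 12), c(1, 2, 3),
                                     n_resamples = 2000, seed = 3,
                                     floor_p = TRUE)
  expect_equal(rf$p_value, 1 / 2001)
})

test_that("shifting one sample upward never increases the permutation p", {
  set.seed(9)
  a <- rnorm(12); b <- rnorm(12)
  ps <- vapply(seq(0, 2, by = 0.25), function(d) {
    permutation_test_independent(a + d, b, n_resamples = 2000,
                                 seed = 42)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("paired bootstrap handles strong, null and degenerate cases", {
  # C clearly above D: all resampled means positive, index = 1
  set.seed(2)
  c1 <- rnorm(19, sd = 0.1) + 10; d1 <- rnorm(19, sd = 0.1)
  r <- bootstrap_paired_test(c1, d1, n_resamples = 2000, seed = 5)
  expect_lte(r$p_value, 0.001)
  expect_equal(r$location_or_index, 1L)
  # exact ties: no resampled mean exceeds zero
  r0 <- bootstrap_paired_test(rep(1, 5), rep(1, 5), seed = 5)
  expect_equal(r0$p_value, 1)
  # determinism
  expect_identical(
    bootstrap_paired_test(c1, d1, 1000, seed = 9)$null_values,
    bootstrap_paired_test(c1, d1, 1000, seed = 9)$null_values)
  expect_error(bootstrap_paired_test(1:3, 1:4), "equal length")
})

test_that("one-way ANOVA matches hand computation and flags clear contrasts", {
  # {1,2,3},{2,3,4},{3,4,5}: SSB = 6 (df 2), SSW = 6 (df 6) => F = 3
  a <- anova_one_way(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(a$F, 3, tolerance = 1e-12)
  expect_equal(unname(a$df), c(2, 6))
  # identical groups: no between-group variance
  a0 <- anova_one_way(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(a0$F, 0, tolerance = 1e-12)
  expect_equal(a0$p, 1, tolerance = 1e-12)
  set.seed(4)
  a2 <- anova_one_way(list(rnorm(4, sd = 0.01), 10 + rnorm(4, sd = 0.01)))
  expect_true(all(a2$pairwise$significant))
  expect_error(anova_one_way(list(1:3)), "two groups")
  expect_error(anova_one_way(list(1:3, 5)), "at least 2 values")
})
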