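test_that("fold-deviation bands partition the ratios", {
  r <- fold_deviation_metrics(c(0.4, 1.0, 2.1, 0.6))
  expect_equal(r$pct_within_2fold, 50)
  expect_equal(r$pct_over_10fold_under, 0)
  expect_equal(r$pct_other, 50)

  expect_equal(fold_deviation_metrics(c(0.01, 100))$log10_spread, 4)

  ones <- fold_deviation_metrics(rep(1, 10))
  expect_equal(ones$pct_within_2fold, 100)
  expect_equal(ones$log10_spread, 0)

  # boundaries: closed 2-fold interval, strict 10-fold-under, zeros under
  edge <- fold_deviation_metrics(c(0.5, 2, 0.1, 0.0999, 0))
  expect_equal(edge$pct_within_2fold, 40)
  expect_equal(edge$pct_over_10fold_under, 40)
  # zeros excluded from the spread
  expect_equal(edge$log10_spread, log10(2 / 0.0999))

  withr::with_seed(4, r2 <- stats::rlnorm(300, 0, 1))
  m <- fold_deviation_metrics(r2)
  expect_equal(m$pct_within_2fold + m$pct_over_10fold_under + m$pct_other,
               100, tolerance = 1e-6)
  expect_error(fold_deviation_metrics(numeric(0)), "no ratios")
  expect_error(fold_deviation_metrics(c(1, -1)), ">= 0")
})

test_that("Mann-Whitney comparison matches permutation enumeration and is symmetric", {
  res <- compare_distributions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, mw_exact_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$method, "exact")

  same <- compare_distributions(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p_value, 1)

  big <- compare_distributions(1:10, 1:10 + 100)
  expect_lt(big$p_value, 0.001)

  # symmetry in the arguments
  withr::with_seed(8, {
    a <- stats::rlnorm(40)
    b <- stats::rlnorm(35, 0.5)
  })
  expect_equal(compare_distributions(a, b)$p_value,
               compare_distributions(b, a)$p_value)
  expect_equal(compare_distributions(a, b)$method, "normal approximation")

  # enumeration agreement on a second unbalanced tie-free case
  a2 <- c(0.1, 0.7, 2.2)
  b2 <- c(0.3, 0.9, 1.4, 1.8, 2.6)
  expect_equal(compare_distributions(a2, b2)$p_value, mw_exact_p(a2, b2))

  expect_error(compare_distributions(numeric(0), 1), "non-empty")
})

test_that("replicate correlation is the squared Pearson coefficient", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(replicate_correlation(x, x), 1)
  expect_equal(replicate_correlation(x, 2 * x + 1), 1)
  expect_equal(replicate_correlation(c(1, 2, 3), c(1, 2, 2)), 0.75)
  expect_error(replicate_correlation(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_error(replicate_correlation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("replicate discrepancy counts 2-fold-or-more pairs with zero clamping", {
  expect_equal(replicate_discrepancy(c(1, 1, 1, 1), c(1, 1, 1, 2.5)), 25)
  expect_equal(replicate_discrepancy(c(1, 2, 3), c(1, 2, 3)), 0)
  # exactly one zero counts as discrepant; double zeros are uninformative
  expect_equal(replicate_discrepancy(c(0, 0, 1), c(1, 0, 1)), 50)
  expect_error(replicate_discrepancy(0, 0), "no informative")
})
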