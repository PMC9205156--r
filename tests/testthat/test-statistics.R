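# Paired t tests, the Holm-Bonferroni step-down and model comparison.

test_that("paired t statistics match their closed forms", {
  r <- paired_ttest(c(2, 3, 4), c(1, 1, 1))       # differences 1, 2, 3
  expect_equal(r$mean_diff, 2)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2L)
  expect_equal(r$p, 2 * pt(-abs(r$t), 2), tolerance = 1e-12)
  same <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p, 1)
})

test_that("paired t is antisymmetric and shift invariant", {
  set.seed(4)
  a <- rnorm(10); b <- rnorm(10)
  r1 <- paired_ttest(a, b)
  r2 <- paired_ttest(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  r3 <- paired_ttest(a + 5, b + 5)
  expect_equal(r1$t, r3$t, tolerance = 1e-10)
})

test_that("paired t agrees with stats::t.test and handles degenerate input", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(3:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    ref <- t.test(a, b, paired = TRUE)
    r <- paired_ttest(a, b)
    expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  }
  # NA pairs are dropped before testing
  r <- paired_ttest(c(1, NA, 3, 5), c(0, 2, NA, 1))
  expect_equal(r$n, 2L)
  expect_error(paired_ttest(c(1, NA), c(0, 2)), ">= 2")
  expect_error(paired_ttest(c(2, 3, 4), c(1, 2, 3)), "degenerate")
})

test_that("the reported recall P values are jointly significant under Holm", {
  h <- holm_bonferroni(c(0.0035, 0.028, 0.0036), alpha = 0.05)
  expect_equal(h$comparisons$rank, c(1L, 3L, 2L))
  expect_equal(h$comparisons$threshold, c(0.05 / 3, 0.05, 0.025))
  expect_true(all(h$comparisons$reject))
})

test_that("the step-down stops at the first failure and beats plain Bonferroni", {
  expect_false(any(holm_bonferroni(c(1, 1))$comparisons$reject))
  h <- holm_bonferroni(c(0.02, 0.03), alpha = 0.05)
  expect_true(all(h$comparisons$reject))         # 0.02 < 0.025, then 0.03 < 0.05
  expect_equal(sum(c(0.02, 0.03) < 0.05 / 2), 1) # Bonferroni rejects only one
  # the first failure blocks later P values even below their own thresholds
  h2 <- holm_bonferroni(c(0.001, 0.03, 0.04), alpha = 0.05)
  expect_equal(h2$comparisons$reject, c(TRUE, FALSE, FALSE))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm matches a brute-force step-down and nests between baselines", {
  set.seed(6)
  for (i in 1:300) {
    m <- sample(1:8, 1)
    p <- round(runif(m), sample(c(1, 2, 3), 1))  # ties are common
    h <- holm_bonferroni(p, alpha = 0.05)
    expect_identical(h$comparisons$reject, brute_holm(p, 0.05))
    bonf <- p < 0.05 / m
    raw <- p < 0.05
    expect_true(all(h$comparisons$reject[bonf]))      # Holm >= Bonferroni
    expect_true(all(raw[h$comparisons$reject]))       # Holm <= uncorrected
    # consistency with stats::p.adjust on ties-free vectors
    if (!anyDuplicated(p))
      expect_identical(h$comparisons$reject,
                       unname(p.adjust(p, "holm") < 0.05))
  }
})

test_that("Holm flags follow the tests under input permutation", {
  set.seed(16)
  p <- runif(6)
  perm <- sample.int(6)
  h1 <- holm_bonferroni(p)
  h2 <- holm_bonferroni(p[perm])
  expect_identical(h2$comparisons$reject, h1$comparisons$reject[perm])
})

test_that("comparing a report with itself finds nothing", {
  rep <- evaluate_loso(fixture("stroke_features", {
    filter_features(tiny_features(), cohort = "stroke")
  }))
  cmp <- compare_models(rep, rep)
  expect_true(all(cmp$table$p == 1))
  expect_false(any(cmp$table$significant_holm))
  # mismatched iteration ids are rejected
  rep2 <- rep
  rep2$iterations$test_unit <- rev(rep2$iterations$test_unit)
  expect_error(compare_models(rep, rep2), "iteration ids")
})
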