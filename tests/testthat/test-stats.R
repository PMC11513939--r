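test_that("one-way ANOVA matches the textbook closed form", {
  toy <- list(a = c(18, 22, 21, 17), b = c(24, 26, 23, 27), c = c(19, 20, 22, 21))
  res <- anova_holm_sidak(toy)
  expect_equal(res$statistic, anova_f_by_hand(toy), tolerance = 1e-12)
  expect_equal(res$p_value,
               pf(anova_f_by_hand(toy), 2, 9, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(nrow(res$comparisons), 3)
  expect_true(all(res$comparisons$p_adjusted >= res$comparisons$p_raw))

  same <- list(g1 = c(1, 2, 3), g2 = c(1, 2, 3), g3 = c(1, 2, 3))
  res0 <- anova_holm_sidak(same)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  sep <- list(a = c(0, 0, 0, 0) + c(-1e-6, 1e-6, 0, 0),
              b = c(1, 1, 1, 1) + c(-1e-6, 1e-6, 0, 0))
  expect_lt(anova_holm_sidak(sep)$p_value, 1e-10)

  expect_error(anova_holm_sidak(list(c(1, 2))), "at least 2")
  expect_error(anova_holm_sidak(list(a = 1, b = c(1, 2))), "at least 2 obs")
})

test_that("ANOVA on two groups agrees with the pooled t-test (F = t^2)", {
  set.seed(14)
  a <- rnorm(12, 100, 10)
  b <- rnorm(9, 110, 10)
  fa <- anova_holm_sidak(list(a = a, b = b))
  tt <- two_group_t(a, b)
  expect_equal(fa$statistic, tt$statistic^2, tolerance = 1e-9)
  expect_equal(fa$p_value, tt$p_value, tolerance = 1e-9)
})

test_that("Holm-Sidak adjustment is monotone and never below raw p", {
  set.seed(5)
  for (i in 1:25) {
    p <- runif(2 + i %% 8)
    adj <- holm_sidak_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
  expect_equal(holm_sidak_adjust(0.05), 0.05)
  expect_error(holm_sidak_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("depth regression detects exact trends and flat nulls", {
  d <- c(10, 20, 30, 40, 50)
  flat <- depth_regression(rep(200, 5), d)
  expect_equal(flat$effect, 0)
  expect_equal(flat$p_value, 1)

  lin <- depth_regression(3 + 2 * d + c(1e-9, -1e-9, 0, 0, 0), d)
  expect_equal(lin$effect, 2, tolerance = 1e-6)
  expect_lt(lin$p_value, 1e-10)

  expect_error(depth_regression(c(1, 2, 3), rep(5, 3)), "constant")
  expect_error(depth_regression(1:2, 1:2), "length >= 3")
})

test_that("simulated depth scenario shows no spurious depth effect", {
  hits <- 0L
  n_seeds <- 12L
  for (s in seq_len(n_seeds)) {
    blocks <- simulate_cohort("depth", list(n = 42L, n_reps = 2000L),
                              seed = 300 + s)
    t1 <- vapply(blocks, function(b)
      fit_double_exponential(build_curve(b))$reported_t1_us, numeric(1))
    depth <- vapply(blocks, function(b) b$meta$depth_um, numeric(1))
    if (depth_regression(t1, depth)$p_value >= 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("ratio paired t-test works on the log scale", {
  b <- c(100, 150, 200, 250, 300)
  eq <- ratio_paired_t(b, b)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(eq$effect, 1)

  dbl <- ratio_paired_t(b, 2 * b)
  expect_equal(dbl$effect, 2)
  expect_equal(dbl$p_value, 0)
  expect_true(dbl$degenerate)

  set.seed(3)
  a <- b * exp(rnorm(5, -0.3, 0.05))
  res <- ratio_paired_t(b, a)
  expect_lt(res$effect, 1)
  # invariance to common rescaling
  res2 <- ratio_paired_t(b * 3.7, a * 3.7)
  expect_equal(res$statistic, res2$statistic, tolerance = 1e-12)
  expect_equal(res$p_value, res2$p_value, tolerance = 1e-12)
  expect_equal(res$effect, res2$effect, tolerance = 1e-12)

  expect_error(ratio_paired_t(c(1, -2), c(1, 2)), "positive")
  expect_error(ratio_paired_t(1:3, 1:2), "equal length")
})

test_that("two-group t-test separates groups and handles degeneracy", {
  same <- two_group_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  res <- two_group_t(c(0, 0, 1e-9, -1e-9), c(10, 10, 10 + 1e-9, 10 - 1e-9))
  expect_lt(res$p_value, 1e-10)
  expect_equal(res$effect, -10, tolerance = 1e-9)

  set.seed(8)
  a <- rnorm(10, 0, 1)
  b <- rnorm(10, 0, 5)
  expect_false(identical(two_group_t(a, b)$p_value,
                         two_group_t(a, b, var_equal = FALSE)$p_value))
  expect_error(two_group_t(1, c(1, 2)), "at least 2")
})

test_that("young versus old cohorts separate in the expected direction", {
  blocks <- simulate_cohort("young_old",
                            list(n_per_group = 12L, n_reps = 2000L), seed = 77)
  t1 <- vapply(blocks, function(b)
    fit_double_exponential(build_curve(b))$reported_t1_us, numeric(1))
  age <- vapply(blocks, function(b) b$meta$age_group, character(1))
  res <- two_group_t(t1[age == "young"], t1[age == "old"])
  expect_gt(res$effect, 0)  # old group has shorter T1 (higher radical load)
})
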