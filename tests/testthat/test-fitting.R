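taus21 <- dark_time_grid(21)$taus_us

test_that("initial parameter heuristic lands near the 1/e crossing", {
  cv <- curve_from_model(taus21, c0 = 1000, a_s = 500, t_s = 100)
  ini <- initial_params(cv)
  expect_gt(ini$t_slow_us, 50)
  expect_lt(ini$t_slow_us, 200)
  expect_equal(ini$t_fast_us, ini$t_slow_us / 10)
  expect_equal(ini$amp_fast / ini$amp_slow, 0.25, tolerance = 1e-9)

  flat <- curve_from_model(taus21, c0 = 500, a_s = 0, t_s = 100)
  expect_error(initial_params(flat), "flat|degenerate")

  four <- curve_from_model(taus21[1:4], c0 = 100, a_s = 50, t_s = 10)
  expect_error(initial_params(four), "at least 5")
})

test_that("noiseless single-exponential data are recovered to 1e-4", {
  cv <- curve_from_model(taus21, c0 = 1000, a_s = 500, t_s = 100)
  fit <- fit_double_exponential(cv)
  expect_true(fit$converged)
  expect_equal(fit$reported_t1_us, 100, tolerance = 1e-4)
  expect_equal(fit$offset_c, 1000, tolerance = 1e-3)
})

test_that("noiseless two-component data recover both time constants", {
  cv <- curve_from_model(taus21, c0 = 20000, a_f = 5000, t_f = 5,
                         a_s = 5000, t_s = 200)
  fit <- fit_double_exponential(cv)
  expect_true(fit$converged)
  expect_equal(fit$t_fast_us, 5, tolerance = 0.01)
  expect_equal(fit$t_slow_us, 200, tolerance = 0.01)
  expect_equal(fit$amp_fast, 5000, tolerance = 0.01)
  expect_equal(fit$amp_slow, 5000, tolerance = 0.01)
  # and beats the brute-force grid oracle's residual
  oracle <- grid_search_dexp(cv$taus_us, cv$pl_counts)
  expect_lte(fit$residual_stat, oracle$resid * (1 + 1e-6) + 1e-9)
})

test_that("T1 is recovered from simulated photon counts", {
  errs <- vapply(1:5, function(s) {
    b <- simulate_block(photophysics(t1_us = 100), background_model(),
                        seed = 100 + s)
    f <- fit_double_exponential(build_curve(b))
    expect_true(f$converged)
    abs(f$reported_t1_us - 100) / 100
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("rescaling dark times rescales the reported T1", {
  cv <- curve_from_model(taus21, c0 = 20000, a_f = 4000, t_f = 5,
                         a_s = 8000, t_s = 150)
  f1 <- fit_double_exponential(cv)
  cv2 <- cv
  cv2$taus_us <- cv$taus_us * 2
  # same counts on a doubled grid = same curve with doubled time constants
  f2 <- fit_double_exponential(cv2)
  expect_equal(f2$reported_t1_us / f1$reported_t1_us, 2, tolerance = 1e-3)
})

test_that("ordering t_fast <= t_slow is structural", {
  for (s in 1:6) {
    b <- simulate_block(photophysics(t1_us = 50 * s), background_model(),
                        seed = 500 + s, n_reps = 3000)
    f <- fit_double_exponential(build_curve(b))
    expect_lte(f$t_fast_us, f$t_slow_us)
    expect_gte(f$amp_fast, 0)
    expect_gte(f$amp_slow, 0)
  }
})

test_that("the 130 us baseline selection rule is inclusive", {
  b <- simulate_block(photophysics(t1_us = 200), background_model(), seed = 1)
  fit <- fit_double_exponential(build_curve(b))
  fit$reported_t1_us <- 130
  expect_true(passes_baseline_filter(fit))
  fit$reported_t1_us <- 129.9
  expect_false(passes_baseline_filter(fit))
  fit$reported_t1_us <- 500
  expect_true(passes_baseline_filter(fit))
  fit$converged <- FALSE
  expect_error(passes_baseline_filter(fit), "converged")
})

test_that("bootstrap CI collapses on degenerate blocks and is deterministic", {
  blk <- constant_block(200, taus21, c0 = 50, a_s = 40, t_s = 150, a_f = 10,
                        t_f = 4)
  fit <- bootstrap_ci(blk, n_boot = 60, seed = 4)
  expect_equal(fit$ci95_halfwidth_pct, 0, tolerance = 1e-9)
  expect_equal(fit$ci95_low_us, fit$ci95_high_us)

  b <- simulate_block(photophysics(), background_model(), seed = 8,
                      n_reps = 3000)
  f1 <- bootstrap_ci(b, n_boot = 60, seed = 99)
  f2 <- bootstrap_ci(b, n_boot = 60, seed = 99)
  expect_identical(f1$ci95_low_us, f2$ci95_low_us)
  expect_identical(f1$ci95_high_us, f2$ci95_high_us)
  expect_true(f1$ci95_low_us <= f1$reported_t1_us &&
                f1$reported_t1_us <= f1$ci95_high_us)
  expect_false(f1$ci_unreliable)

  expect_error(bootstrap_ci(b, n_boot = 10, seed = 1), "at least 50")
})
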