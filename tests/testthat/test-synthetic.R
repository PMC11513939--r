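test_that("trigger trajectories follow the single-exponential approach", {
  expect_equal(t1_at(trigger_spec("medium"), 200, c(0, 5, 50)), rep(200, 3))

  eth <- trigger_spec("ethanol", delta = -0.4)
  expect_equal(t1_at(eth, 200, 1e6), 0.6 * 200, tolerance = 1e-12)

  asc <- trigger_spec("ascorbate", delta = 0.5, response_tau_min = 5)
  expect_equal(t1_at(asc, 200, 5), 200 * (1 + 0.5 * (1 - exp(-1))))

  late <- trigger_spec("ethanol", onset_min = 10)
  expect_equal(t1_at(late, 200, 9.9), 200)
  expect_lt(t1_at(late, 200, 10.1), 200)

  expect_error(trigger_spec("ethanol", delta = -1), "delta")
  expect_error(t1_at(eth, -5, 1), "positive")
})

test_that("expected readout counts match the closed-form mean model", {
  spec <- default_spec
  bg0 <- background_model(0, 0, 5)
  phot <- photophysics(bright_rate_cps = 1e6, contrast = 0.3, t1_us = 100,
                       fast_fraction = 0)
  rw <- spec$read_window_us * 1e-6
  # tau -> 0: fully polarized, no contrast loss
  expect_equal(expected_readout_counts(1e-9, 0, phot, bg0, spec), 1e6 * rw,
               tolerance = 1e-6)
  # tau -> Inf: spin equilibrium
  expect_equal(expected_readout_counts(1e9, 0, phot, bg0, spec),
               1e6 * (1 - 0.3) * rw)
  # tau = T1
  expect_equal(expected_readout_counts(100, 0, phot, bg0, spec),
               1e6 * (1 - 0.3 * (1 - exp(-1))) * rw)
  # background adds b(t) * read window
  bg <- background_model(4e5, 1e5, 5)
  expect_equal(expected_readout_counts(100, 5, phot, bg, spec) -
                 expected_readout_counts(100, 5, phot, bg0, spec),
               (1e5 + 3e5 * exp(-1)) * rw)
})

test_that("mean counts decrease with dark time and with shorter T1", {
  spec <- default_spec
  bg <- background_model()
  taus <- spec$grid$taus_us
  mu <- expected_readout_counts(taus, 0, photophysics(), bg, spec)
  expect_true(all(diff(mu) < 0))
  mu_short <- expected_readout_counts(taus, 0, photophysics(t1_us = 50), bg, spec)
  expect_true(all(mu_short[-1] < mu[-1]))  # tau > 0 strictly lower
})

test_that("simulation is deterministic in the seed and matches its mean model", {
  phot <- photophysics()
  bg <- background_model(3e5, 3e5, 5)  # constant background
  b1 <- simulate_block(phot, bg, seed = 42, n_reps = 10000)
  b2 <- simulate_block(phot, bg, seed = 42, n_reps = 10000)
  expect_identical(b1$counts, b2$counts)
  b3 <- simulate_block(phot, bg, seed = 43, n_reps = 10000)
  expect_false(identical(b1$counts, b3$counts))

  # empirical column means within 4 SE of the analytic means
  mu <- expected_readout_counts(default_spec$grid$taus_us, 0, phot, bg,
                                default_spec)
  se <- sqrt(mu / 10000)
  expect_true(all(abs(colMeans(b1$counts) - mu) < 4 * se))

  # bright scene with mu(tau_min) = 50 counts: means within 1% of the model
  bright <- photophysics(bright_rate_cps = 5e7)
  bb <- simulate_block(bright, background_model(0, 0, 5), seed = 44,
                       n_reps = 10000)
  mu_b <- expected_readout_counts(default_spec$grid$taus_us, 0, bright,
                                  background_model(0, 0, 5), default_spec)
  expect_equal(mu_b[1], 50, tolerance = 0.01)
  expect_true(all(abs(colMeans(bb$counts) - mu_b) / mu_b < 0.01))
})

test_that("without spin contrast all dark times look alike", {
  phot <- photophysics(contrast = 1e-9)
  bg <- background_model(0, 0, 5)
  b <- simulate_block(phot, bg, seed = 7, n_reps = 5000)
  mu <- photophysics()$bright_rate_cps * 1e-6
  se <- sqrt(mu / 5000)
  expect_true(all(abs(colMeans(b$counts) - mu) < 4 * se))
})

test_that("background-only blocks bleach over time", {
  phot <- photophysics(bright_rate_cps = 1e-6)  # negligible FND signal
  bg <- background_model(b0_cps = 1e6, binf_cps = 1e5, bleach_tau_min = 2)
  b <- simulate_block(phot, bg, seed = 11, n_reps = 20000)  # 4 minutes
  tot <- rowSums(b$counts)
  half <- length(tot) / 2
  expect_gt(mean(tot[1:half]), mean(tot[(half + 1):length(tot)]))
})

test_that("cohort scenarios carry the right structure", {
  small <- list(n_reps = 50L)
  loc <- simulate_cohort("locations", small, seed = 5)
  expect_length(loc, 42)
  expect_setequal(unique(vapply(loc, function(b) b$meta$location, numeric(1))),
                  1:3)
  expect_true(all(vapply(loc, function(b) nrow(b$counts), numeric(1)) == 50))

  dep <- simulate_cohort("depth", small, seed = 5)
  depths <- vapply(dep, function(b) b$meta$depth_um, numeric(1))
  expect_true(all(depths >= 0 & depths <= 75))

  yo <- simulate_cohort("young_old", c(small, list(n_per_group = 6L)), seed = 5)
  ages <- vapply(yo, function(b) b$meta$age_group, character(1))
  expect_identical(as.vector(table(ages)[c("young", "old")]), c(6L, 6L))

  tp <- simulate_cohort("trigger_panel", c(small, list(n_per_kind = 2L)), seed = 5)
  kinds <- vapply(tp, function(b) b$meta$trigger_kind, character(1))
  expect_identical(sort(unique(kinds)), c("ascorbate", "ethanol", "medium"))
  expect_true(all(table(kinds) == 2))
  expect_error(simulate_cohort("banana", seed = 1), "arg")
})

test_that("drawn T1s differ by seed but share the distribution", {
  p <- list(n = 30L, n_reps = 10L)
  a <- simulate_cohort("locations", p, seed = 1)
  b <- simulate_cohort("locations", p, seed = 2)
  ta <- vapply(a, function(x) x$meta$t1_true_us, numeric(1))
  tb <- vapply(b, function(x) x$meta$t1_true_us, numeric(1))
  expect_false(identical(ta, tb))
  # same lognormal: medians within a factor reflecting GSD 1.4 sampling noise
  expect_lt(abs(log(median(ta) / median(tb))), 3 * log(1.4) / sqrt(30) * 3)
})
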