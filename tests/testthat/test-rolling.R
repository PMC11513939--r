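test_that("rolling scheme enumerates the documented windows", {
  w1 <- rolling_windows(50000, 50000, 10000)
  expect_length(w1, 1)
  expect_equal(w1[[1]]$start_rep, 0)
  expect_equal(w1[[1]]$end_rep, 50000)

  # 33-minute recording: 12 windows, first spanning minutes 0-10,
  # the last snapped flush to the end (minutes 23-33)
  w <- rolling_windows(165000, 50000, 10000)
  expect_length(w, 12)
  spec <- pulse_seq_spec()
  expect_equal(unname(rep_window_to_minutes(w[[1]], spec)), c(0, 10))
  expect_equal(unname(rep_window_to_minutes(w[[2]], spec)), c(2, 12))
  expect_equal(unname(rep_window_to_minutes(w[[12]], spec)), c(23, 33))

  expect_error(rolling_windows(40000, 50000, 10000), "shorter")
})

test_that("rolling T1 labels windows by end time and matches a direct fit", {
  blk <- constant_block(12000, c0 = 40, a_s = 30, t_s = 150, a_f = 8)
  tr <- rolling_t1(blk, window_reps = 5000, step_reps = 2000)
  expect_length(tr$t1_us, 4)  # floor((12000-5000)/2000)+1
  expect_equal(tr$times_min,
               c(5000, 7000, 9000, 12000) * 0.012 / 60)
  direct <- fit_double_exponential(build_curve(blk, rep_window(0, 5000)))
  expect_identical(tr$t1_us[1], direct$reported_t1_us)
  expect_true(all(tr$converged))
})

test_that("baseline normalization prepends the -1 min reference point", {
  blk <- constant_block(6000, c0 = 40, a_s = 30, t_s = 150, a_f = 8)
  tr <- rolling_t1(blk, window_reps = 5000, step_reps = 1000)
  nt <- normalize_to_baseline(tr, 200)
  expect_equal(nt$times_min[1], -1)
  expect_equal(nt$normalized[1], 1)
  expect_equal(nt$normalized[-1], tr$t1_us / 200)
  expect_true(all(diff(nt$times_min) > 0))

  tr2 <- tr
  tr2$t1_us <- c(200, 150)
  tr2$times_min <- c(1, 2)
  tr2$converged <- c(TRUE, TRUE)
  nt2 <- normalize_to_baseline(tr2, 200)
  expect_equal(nt2$normalized, c(1, 1, 0.75))

  expect_error(normalize_to_baseline(tr, -5), "positive")
})

test_that("replicate traces summarize to medians and quartiles", {
  mk <- function(vals) {
    structure(list(times_min = seq_along(vals), t1_us = vals,
                   converged = rep(TRUE, length(vals)),
                   normalized = NULL, baseline_t1_us = NA_real_,
                   window_reps = 10, step_reps = 5, windows = NULL),
              class = "t1_trace")
  }
  five <- replicate(5, mk(c(200, 180, 160)), simplify = FALSE)
  s <- summarize_traces(five)
  expect_equal(s$median, c(200, 180, 160))
  expect_equal(s$q75 - s$q25, rep(0, 3))

  spread <- lapply(1:5, function(i) mk(i))
  s2 <- summarize_traces(spread)
  expect_equal(s2$median, 3)
  expect_equal(s2$q25, 2)
  expect_equal(s2$q75, 4)

  bad <- c(five, list(mk(c(1, 2))))
  expect_error(summarize_traces(bad), "time grid")
})

test_that("a strong ethanol trigger drags the normalized trace below 1", {
  res <- run_trigger_experiment(
    trigger = trigger_spec("ethanol", delta = -0.4, response_tau_min = 4),
    seed = 21, baseline_reps = 5000, n_reps = 30000,
    window_reps = 10000, step_reps = 5000)
  norm <- res$trace$normalized
  expect_lt(norm[length(norm)], 1)
  expect_lt(res$final_t1_us, res$baseline_fit$reported_t1_us)
  expect_true(passes_baseline_filter(res$baseline_fit))
})
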