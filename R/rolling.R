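#' Enumerate rolling summation windows
#'
#' Windows of `window_reps` repetitions advanced by `step_reps`:
#' \eqn{K = \lfloor (N - W)/S \rfloor + 1} windows starting at multiples
#' of the step, with the final window's start snapped to \eqn{N - W} so
#' the scheme ends flush with the recording.
#'
#' @param n_reps Total repetitions `N` in the recording.
#' @param window_reps Window length `W`.
#' @param step_reps Step `S` between window starts.
#' @return List of [rep_window()]s.
#' @export
rolling_windows <- function(n_reps, window_reps, step_reps) {
  if (n_reps < window_reps)
    stop(sprintf("recording of %d repetitions is shorter than one window of %d",
                 n_reps, window_reps), call. = FALSE)
  if (step_reps < 1) stop_invalid("`step_reps` must be positive")
  k_max <- floor((n_reps - window_reps) / step_reps) + 1
  starts <- (seq_len(k_max) - 1) * step_reps
  starts[k_max] <- n_reps - window_reps  # final window reaches the last data
  lapply(starts, function(s) rep_window(s, s + window_reps))
}

#' Time-resolved T1 via the rolling summation window
#'
#' Re-sums a long recording with an overlapping window scheme: the first
#' `window_reps` repetitions give one T1 value, then the summation window
#' is shifted by `step_reps`, and so on until the window reaches the last
#' data. With the defaults (window 50,000, step 10,000, 2 min per 10,000
#' repetitions) the first window spans minutes 0-10 and the second minutes
#' 2-12. The number of windows is
#' \eqn{K = \lfloor (N - W)/S \rfloor + 1}; when \eqn{N - W} is not a
#' multiple of \eqn{S} the final window's start is snapped to \eqn{N - W}
#' so it ends flush with the recording. Each window's curve is fitted with
#' [fit_double_exponential()]; the time label of a window is its end time
#' in minutes (the latest information time).
#'
#' @param block A sweep block with at least `window_reps` repetitions.
#' @param window_reps Summation window length in repetitions.
#' @param step_reps Shift between successive windows.
#' @param options A [fit_options()].
#' @return An object of class `t1_trace`: `times_min`, `t1_us`,
#'   `converged`, the scheme parameters, and the windows used.
#' @export
rolling_t1 <- function(block, window_reps = 50000, step_reps = 10000,
                       options = fit_options()) {
  stopifnot(inherits(block, "sweep_block"))
  n <- nrow(block$counts)
  if (n < window_reps)
    stop(sprintf("block has %d repetitions; at least one full window of %d is required",
                 n, window_reps), call. = FALSE)
  t0 <- if (!is.null(block$truth$t0_min)) block$truth$t0_min else 0
  windows <- rolling_windows(n, window_reps, step_reps)
  starts <- vapply(windows, function(w) w$start_rep, numeric(1))
  fits <- lapply(windows, function(w)
    tryCatch(fit_double_exponential(build_curve(block, w), options),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  structure(list(
    times_min = t0 + (starts + window_reps) * block$spec$sweep_period_s / 60,
    t1_us = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$reported_t1_us,
                   numeric(1)),
    converged = vapply(fits, function(f) !is.null(f) && f$converged, logical(1)),
    normalized = NULL, baseline_t1_us = NA_real_,
    window_reps = window_reps, step_reps = step_reps,
    windows = windows),
    class = "t1_trace")
}

#' Normalize a T1 trace to its pre-trigger baseline
#'
#' Divides every T1 value by the baseline T1 recorded from the same FND
#' before the trigger was added, and prepends a synthetic baseline point
#' at time -1 min with normalized value 1 (the convention used when
#' plotting trigger responses).
#'
#' @param trace A [rolling_t1()] result.
#' @param baseline_t1_us Baseline T1 in µs (from a separate pre-trigger
#'   fit).
#' @return The trace with `normalized`, `baseline_t1_us` and the leading
#'   baseline point filled in.
#' @export
normalize_to_baseline <- function(trace, baseline_t1_us) {
  stopifnot(inherits(trace, "t1_trace"))
  if (!is.numeric(baseline_t1_us) || length(baseline_t1_us) != 1L ||
      !is.finite(baseline_t1_us) || baseline_t1_us <= 0)
    stop_invalid("`baseline_t1_us` must be a positive number")
  out <- trace
  out$times_min <- c(-1, trace$times_min)
  out$t1_us <- c(baseline_t1_us, trace$t1_us)
  out$converged <- c(TRUE, trace$converged)
  out$normalized <- out$t1_us / baseline_t1_us
  out$baseline_t1_us <- baseline_t1_us
  out
}

#' @export
print.t1_trace <- function(x, ...) {
  cat(sprintf("T1 trace: %d windows (W = %d, S = %d reps), %.3g to %.3g min\n",
              length(x$times_min), x$window_reps, x$step_reps,
              min(x$times_min), max(x$times_min)))
  invisible(x)
}

#' @export
as.data.frame.t1_trace <- function(x, ...) {
  d <- data.frame(time_min = x$times_min, t1_us = x$t1_us,
                  converged = x$converged)
  if (!is.null(x$normalized)) d$t1_normalized <- x$normalized
  d
}

#' Plot a T1 trace
#'
#' @param x A `t1_trace`; normalized values are plotted when present.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.t1_trace <- function(x, ...) {
  if (!is.null(x$normalized)) {
    graphics::plot(x$times_min, x$normalized, type = "b",
                   xlab = "time (min)", ylab = expression(T[1]/T[1 * ",baseline"]), ...)
    graphics::abline(h = 1, lty = 3)
  } else {
    graphics::plot(x$times_min, x$t1_us, type = "b",
                   xlab = "time (min)", ylab = expression(T[1] ~ "(µs)"), ...)
  }
  invisible(x)
}

#' Median and interquartile range across replicate traces
#'
#' Summarizes replicate T1 traces (for example the five independent
#' measurements of one trigger condition) per timepoint: the median and
#' the 25-75 percentile range. Normalized values are summarized when all
#' traces carry them.
#'
#' @param traces List of [rolling_t1()] / [normalize_to_baseline()]
#'   results sharing one time grid.
#' @return Data frame with `time_min`, `median`, `q25`, `q75`, `n`.
#' @export
summarize_traces <- function(traces) {
  if (!length(traces) || !all(vapply(traces, inherits, logical(1), "t1_trace")))
    stop_invalid("`traces` must be a non-empty list of t1_trace objects")
  tg <- traces[[1L]]$times_min
  same <- vapply(traces, function(x)
    length(x$times_min) == length(tg) && all(abs(x$times_min - tg) < 1e-9),
    logical(1))
  if (!all(same)) stop_invalid("traces do not share the same time grid")
  use_norm <- all(vapply(traces, function(x) !is.null(x$normalized), logical(1)))
  vals <- vapply(traces, function(x) if (use_norm) x$normalized else x$t1_us,
                 numeric(length(tg)))
  vals <- matrix(vals, nrow = length(tg))
  data.frame(
    time_min = tg,
    median = apply(vals, 1, stats::median, na.rm = TRUE),
    q25 = apply(vals, 1, stats::quantile, probs = 0.25, na.rm = TRUE, names = FALSE),
    q75 = apply(vals, 1, stats::quantile, probs = 0.75, na.rm = TRUE, names = FALSE),
    n = apply(vals, 1, function(v) sum(is.finite(v))))
}

#' Simulate and analyze one trigger experiment end to end
#'
#' Reproduces the full single-FND workflow of a trigger recording: a
#' pre-trigger baseline curve is recorded and fitted (and checked against
#' the 130 µs baseline selection rule), the trigger is added, a long
#' recording is simulated, analyzed with the rolling window, and the trace
#' normalized to the baseline.
#'
#' @param phot,bg,spec Simulation models (see [simulate_block()]).
#' @param trigger A [trigger_spec()].
#' @param seed Integer seed.
#' @param baseline_reps Repetitions of the baseline recording.
#' @param n_reps Repetitions of the triggered recording (165,000 = 33 min
#'   by default).
#' @param window_reps,step_reps Rolling-window scheme.
#' @param enforce_baseline Apply the 130 µs selection rule to the baseline
#'   fit (error if the particle fails).
#' @param options A [fit_options()].
#' @return List with `baseline_fit`, the normalized `trace`, and
#'   `final_t1_us` (the last window's T1).
#' @export
run_trigger_experiment <- function(phot = photophysics(), bg = background_model(),
                                   trigger = trigger_spec("medium"),
                                   spec = pulse_seq_spec(), seed,
                                   baseline_reps = 10000, n_reps = 165000,
                                   window_reps = 50000, step_reps = 10000,
                                   enforce_baseline = FALSE,
                                   options = fit_options()) {
  if (missing(seed)) stop_invalid("`seed` is required")
  base_block <- simulate_block(phot, bg, trigger_spec("medium"), spec,
                               n_reps = baseline_reps,
                               seed = derive_seed(seed, 1))
  baseline_fit <- fit_double_exponential(build_curve(base_block), options)
  if (enforce_baseline && !passes_baseline_filter(baseline_fit))
    stop(sprintf("particle excluded: baseline T1 %.1f us is below the 130 us rule",
                 baseline_fit$reported_t1_us), call. = FALSE)
  block <- simulate_block(phot, bg, trigger, spec, n_reps = n_reps,
                          seed = derive_seed(seed, 2))
  trace <- rolling_t1(block, window_reps, step_reps, options)
  trace <- normalize_to_baseline(trace, baseline_fit$reported_t1_us)
  list(baseline_fit = baseline_fit, trace = trace,
       final_t1_us = trace$t1_us[length(trace$t1_us)])
}
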