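#' Logarithmically spaced dark-time grid
#'
#' Constructs the grid of dark times \eqn{\tau} used in a pulsed T1
#' relaxometry sweep. During one repetition of the sequence, the laser is
#' switched off for each dark time in turn; the grid is geometrically
#' (log-uniformly) spaced between `tau_min_us` and `tau_max_us`, both
#' included. The default grid spans 0.2 µs to 2 ms in 21 points.
#'
#' @param n_points Number of dark times (at least 2).
#' @param tau_min_us Shortest dark time, in microseconds.
#' @param tau_max_us Longest dark time, in microseconds.
#' @return An object of class `dark_time_grid`: a list with `taus_us`
#'   (strictly increasing dark times, µs) and `n_points`.
#' @examples
#' g <- dark_time_grid(3, 0.2, 2000)
#' g$taus_us # 0.2, 20, 2000
#' @export
dark_time_grid <- function(n_points = 21L, tau_min_us = 0.2, tau_max_us = 2000) {
  if (!is_count(n_points) || n_points < 2)
    stop_invalid("`n_points` must be an integer >= 2, got %s", format(n_points))
  if (!is.numeric(tau_min_us) || !is.numeric(tau_max_us) ||
      tau_min_us <= 0 || tau_max_us <= 0)
    stop_invalid("dark-time bounds must be positive")
  if (tau_min_us >= tau_max_us)
    stop_invalid("`tau_min_us` must be smaller than `tau_max_us`")
  taus <- exp(seq(log(tau_min_us), log(tau_max_us), length.out = n_points))
  taus[1L] <- tau_min_us
  taus[n_points] <- tau_max_us
  structure(list(taus_us = taus, n_points = as.integer(n_points)),
            class = "dark_time_grid")
}

#' @export
print.dark_time_grid <- function(x, ...) {
  cat(sprintf("Dark-time grid: %d points, %.3g to %.4g us (log-spaced)\n",
              x$n_points, x$taus_us[1L], x$taus_us[x$n_points]))
  invisible(x)
}

#' Pulse-sequence specification
#'
#' Describes the geometry and timing of the T1 pulse sequence: 5 µs laser
#' pulses separated by the dark times of `grid`, with the photon counts
#' integrated over the first `read_window_us` of each pulse serving as the
#' readout. `sweep_period_s` is the modeled wall-clock duration of one full
#' sweep over all dark times (one "repetition" in the sense of the rolling
#' window); the default 0.012 s calibrates 10,000 repetitions to 2 minutes.
#'
#' @param pulse_len_us Laser pulse length in µs.
#' @param read_window_us Readout integration window in µs (not longer than
#'   the pulse).
#' @param grid A [dark_time_grid()].
#' @param n_reps_per_curve Repetitions accumulated for one standard
#'   relaxation curve.
#' @param sweep_period_s Wall-clock seconds per repetition (one sweep over
#'   all dark times, including hardware overhead).
#' @param pulse_energy_nJ Nominal energy per pulse (metadata only).
#' @return An object of class `pulse_seq_spec`.
#' @export
pulse_seq_spec <- function(pulse_len_us = 5, read_window_us = 1,
                           grid = dark_time_grid(),
                           n_reps_per_curve = 10000L,
                           sweep_period_s = 0.012,
                           pulse_energy_nJ = 0.3) {
  if (!inherits(grid, "dark_time_grid"))
    stop_invalid("`grid` must be a dark_time_grid")
  if (read_window_us > pulse_len_us)
    stop_invalid("read window (%g us) cannot exceed the pulse length (%g us)",
                 read_window_us, pulse_len_us)
  if (!is_count(n_reps_per_curve) || n_reps_per_curve < 1)
    stop_invalid("`n_reps_per_curve` must be a positive integer")
  spec <- structure(
    list(pulse_len_us = pulse_len_us, read_window_us = read_window_us,
         grid = grid, n_reps_per_curve = as.integer(n_reps_per_curve),
         sweep_period_s = sweep_period_s, pulse_energy_nJ = pulse_energy_nJ),
    class = "pulse_seq_spec")
  if (sweep_period_s < minimum_sweep_period(spec))
    stop_invalid("sweep_period_s = %g s is shorter than the physical minimum %g s",
                 sweep_period_s, minimum_sweep_period(spec))
  spec
}

#' Minimum physically possible sweep period
#'
#' Sum of all laser pulses and all dark times of one sweep, in seconds. The
#' configured `sweep_period_s` must be at least this long; the difference is
#' unmodeled hardware overhead.
#'
#' @param spec A [pulse_seq_spec()].
#' @return Seconds (scalar).
#' @export
minimum_sweep_period <- function(spec) {
  stopifnot(inherits(spec, "pulse_seq_spec"))
  (spec$grid$n_points * spec$pulse_len_us + sum(spec$grid$taus_us)) * 1e-6
}

#' Repetition window
#'
#' Half-open, 0-based window of repetition indices `[start_rep, end_rep)`,
#' the "summation window" over which readout counts are summed into one
#' relaxation curve.
#'
#' @param start_rep First repetition index (0-based, inclusive).
#' @param end_rep One past the last repetition index (exclusive).
#' @return An object of class `rep_window`.
#' @export
rep_window <- function(start_rep, end_rep) {
  if (!is_count(start_rep) || !is_count(end_rep))
    stop_invalid("window bounds must be integers")
  if (start_rep < 0 || start_rep >= end_rep)
    stop_invalid("need 0 <= start_rep < end_rep, got [%s, %s)",
                 format(start_rep), format(end_rep))
  structure(list(start_rep = as.double(start_rep), end_rep = as.double(end_rep)),
            class = "rep_window")
}

#' Map a repetition window to experiment minutes
#'
#' Repetition index `i` begins at wall-clock time `i * sweep_period_s`
#' seconds; with the default 0.012 s period, 10,000 repetitions correspond
#' to 2 minutes, so the first 50,000-repetition window spans minutes 0 to
#' 10 and shifting it by 10,000 repetitions gives minutes 2 to 12.
#'
#' @param window A [rep_window()].
#' @param spec A [pulse_seq_spec()].
#' @return Numeric vector `c(t_start_min, t_end_min)`.
#' @examples
#' rep_window_to_minutes(rep_window(0, 50000), pulse_seq_spec()) # 0 10
#' @export
rep_window_to_minutes <- function(window, spec) {
  stopifnot(inherits(window, "rep_window"), inherits(spec, "pulse_seq_spec"))
  c(t_start_min = window$start_rep * spec$sweep_period_s / 60,
    t_end_min = window$end_rep * spec$sweep_period_s / 60)
}
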