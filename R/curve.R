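#' Build a relaxation curve PL(tau)
#'
#' Sums the readout counts of a sweep block over a repetition window,
#' giving the photoluminescence PL(\eqn{\tau}) relaxation curve used for
#' T1 fitting. Summation is exact integer arithmetic; raw summed counts
#' (not per-repetition means) are kept so Poisson weighting in the fit is
#' exact.
#'
#' @param block A [simulate_block()] result (or a block read from disk).
#' @param window A [rep_window()]; default is the whole block.
#' @return An object of class `relaxation_curve`: `taus_us`, `pl_counts`
#'   (summed counts per dark time), `n_reps`, `window`, `t_center_min`.
#' @export
build_curve <- function(block, window = NULL) {
  stopifnot(inherits(block, "sweep_block"))
  n <- nrow(block$counts)
  if (is.null(window)) window <- rep_window(0, n)
  stopifnot(inherits(window, "rep_window"))
  if (window$end_rep > n)
    stop(sprintf("window [%d, %d) is out of bounds for a block with %d repetitions",
                 window$start_rep, window$end_rep, n), call. = FALSE)
  rows <- (window$start_rep + 1):window$end_rep
  pl <- if (length(rows) == 1L) as.double(block$counts[rows, ]) else
    colSums(block$counts[rows, , drop = FALSE])
  t0 <- if (!is.null(block$truth$t0_min)) block$truth$t0_min else 0
  tc <- t0 + (window$start_rep + window$end_rep) / 2 * block$spec$sweep_period_s / 60
  structure(list(taus_us = block$spec$grid$taus_us, pl_counts = pl,
                 n_reps = window$end_rep - window$start_rep,
                 window = window, t_center_min = tc, spec = block$spec),
            class = "relaxation_curve")
}

#' Normalize a relaxation curve to its first bin
#'
#' Display-only normalization PL(\eqn{\tau}) / PL(\eqn{\tau_{min}});
#' fitting always uses the raw counts.
#'
#' @param curve A [build_curve()] result.
#' @return Numeric vector with first element exactly 1.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "relaxation_curve"))
  if (curve$pl_counts[1L] <= 0)
    stop_invalid("cannot normalize: first bin has zero counts")
  curve$pl_counts / curve$pl_counts[1L]
}

#' @export
print.relaxation_curve <- function(x, ...) {
  cat(sprintf("Relaxation curve: %d dark times, %d repetitions summed, window [%d, %d)\n",
              length(x$taus_us), x$n_reps, x$window$start_rep, x$window$end_rep))
  invisible(x)
}

#' Plot a relaxation curve
#'
#' PL(\eqn{\tau}) against dark time on a log-\eqn{\tau} axis, optionally
#' with a fitted double-exponential overlay.
#'
#' @param x A `relaxation_curve`.
#' @param fit Optional [fit_double_exponential()] result to overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.relaxation_curve <- function(x, fit = NULL, ...) {
  graphics::plot(x$taus_us, x$pl_counts, log = "x",
                 xlab = expression(tau ~ "(µs)"),
                 ylab = "PL (summed counts)", ...)
  if (!is.null(fit)) {
    tt <- exp(seq(log(min(x$taus_us)), log(max(x$taus_us)), length.out = 200))
    graphics::lines(tt, predict_dexp(fit, tt), col = 2)
  }
  invisible(x)
}
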