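# Shared fixture builders: everything is generated in code at test time.

default_spec <- pulse_seq_spec()

# A sweep block built directly from a counts matrix (bypasses the simulator,
# for exact-arithmetic and degenerate-input tests).
block_from_counts <- function(counts, spec = NULL) {
  if (is.null(spec)) {
    grid <- dark_time_grid(ncol(counts))
    spec <- pulse_seq_spec(grid = grid)
  }
  structure(list(counts = counts, spec = spec, truth = NULL, meta = list()),
            class = "sweep_block")
}

# Noiseless relaxation curve straight from double-exponential model values.
curve_from_model <- function(taus, c0, a_f = 0, t_f = 1, a_s, t_s,
                             n_reps = 1000L, round_counts = FALSE) {
  y <- c0 + a_f * exp(-taus / t_f) + a_s * exp(-taus / t_s)
  if (round_counts) y <- round(y)
  structure(list(taus_us = taus, pl_counts = y, n_reps = n_reps,
                 window = rep_window(0, n_reps), t_center_min = 0,
                 spec = pulse_seq_spec(grid = dark_time_grid(length(taus)))),
            class = "relaxation_curve")
}

# Independent trapezoid integral of a spectrum's density.
trapz_check <- function(sp) {
  x <- sp$wavelength_nm
  y <- sp$density
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

# Constant-rows block whose row is a plausible integer relaxation profile;
# cheap to build at any length, deterministic, and fit-able after summation.
constant_block <- function(n_reps, taus = dark_time_grid()$taus_us,
                           c0 = 10, a_s = 8, t_s = 150, a_f = 2, t_f = 4) {
  row <- as.integer(round(c0 + a_f * exp(-taus / t_f) + a_s * exp(-taus / t_s)))
  counts <- matrix(rep(row, each = n_reps), nrow = n_reps)
  block_from_counts(counts,
                    pulse_seq_spec(grid = dark_time_grid(length(taus))))
}
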