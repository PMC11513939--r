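#' FND photophysics parameters
#'
#' Spin-dependent photoluminescence model of a fluorescent nanodiamond
#' (FND). At zero dark time the NV ensemble is fully polarized into the
#' bright ms = 0 state and emits at `bright_rate_cps` (detected counts per
#' second within the readout window, after all filters). As the spins relax
#' toward thermal equilibrium the emission drops by the fraction `contrast`.
#' Relaxation is modeled as a two-component exponential: a slow component
#' with time constant `t1_us` (the spin T1, the quantity of interest, which
#' is shortened by nearby free radicals) and an optional fast component
#' (`t1_fast_us`, weight `fast_fraction`) standing in for short-dark-time
#' photophysics such as NV charge-state dynamics — the reason relaxation
#' curves are routinely fitted with a double exponential.
#'
#' `t1_us` may be a function of time (minutes) to describe a drifting T1.
#'
#' @param bright_rate_cps Detected FND photon rate at \eqn{\tau \to 0}
#'   (counts/s within the read window, after filtering).
#' @param contrast Relative fluorescence drop from ms = 0 to spin
#'   equilibrium, in (0, 1).
#' @param t1_us Ground-truth slow relaxation time in µs, or a function of
#'   time in minutes returning it.
#' @param t1_fast_us Fast-component time constant in µs.
#' @param fast_fraction Weight of the fast component, in \[0, 1).
#' @return An object of class `photophysics`.
#' @export
photophysics <- function(bright_rate_cps = 2e6, contrast = 0.3,
                         t1_us = 200, t1_fast_us = 4, fast_fraction = 0.2) {
  if (bright_rate_cps <= 0) stop_invalid("`bright_rate_cps` must be positive")
  if (contrast <= 0 || contrast >= 1) stop_invalid("`contrast` must be in (0, 1)")
  if (!is.function(t1_us) && any(t1_us <= 0)) stop_invalid("`t1_us` must be positive")
  if (t1_fast_us <= 0) stop_invalid("`t1_fast_us` must be positive")
  if (fast_fraction < 0 || fast_fraction >= 1)
    stop_invalid("`fast_fraction` must be in [0, 1)")
  structure(list(bright_rate_cps = bright_rate_cps, contrast = contrast,
                 t1_us = t1_us, t1_fast_us = t1_fast_us,
                 fast_fraction = fast_fraction),
            class = "photophysics")
}

t1_base_at <- function(phot, t_min) {
  if (is.function(phot$t1_us)) phot$t1_us(t_min) else rep_len(phot$t1_us, length(t_min))
}

#' Tissue autofluorescence background model
#'
#' Autofluorescence entering the detection band, modeled as a rate that
#' photobleaches exponentially over minutes from `b0_cps` toward the
#' non-bleachable floor `binf_cps`. The background is dark-time independent
#' (it only offsets the relaxation curve) but time dependent.
#'
#' @param b0_cps Initial background rate (counts/s within the read window,
#'   after filtering).
#' @param binf_cps Non-bleachable floor rate.
#' @param bleach_tau_min Bleaching time constant in minutes.
#' @return An object of class `background_model`.
#' @export
background_model <- function(b0_cps = 4e5, binf_cps = 1e5, bleach_tau_min = 5) {
  if (binf_cps < 0 || b0_cps < binf_cps)
    stop_invalid("need b0_cps >= binf_cps >= 0")
  if (bleach_tau_min <= 0) stop_invalid("`bleach_tau_min` must be positive")
  structure(list(b0_cps = b0_cps, binf_cps = binf_cps,
                 bleach_tau_min = bleach_tau_min),
            class = "background_model")
}

background_at <- function(bg, t_min) {
  bg$binf_cps + (bg$b0_cps - bg$binf_cps) * exp(-t_min / bg$bleach_tau_min)
}

#' Chemical trigger acting on T1
#'
#' Describes an intervention added to the medium at `onset_min`: ethanol
#' raises the free-radical load and lowers T1 (`delta < 0`), L-ascorbic
#' acid scavenges radicals and raises T1 (`delta > 0`), and plain medium is
#' the negative control (`delta = 0`). T1 approaches its new steady state
#' `t1_base * (1 + delta)` exponentially with time constant
#' `response_tau_min`.
#'
#' @param kind One of `"medium"`, `"ethanol"`, `"ascorbate"`.
#' @param delta Fractional steady-state change of T1 (> -1). Defaults by
#'   kind: -0.4 (ethanol), 0 (medium), +0.4 (ascorbate).
#' @param response_tau_min Approach time constant in minutes.
#' @param onset_min Time at which the trigger is added (minutes).
#' @return An object of class `trigger_spec`.
#' @export
trigger_spec <- function(kind = c("medium", "ethanol", "ascorbate"),
                         delta = NULL, response_tau_min = 8, onset_min = 0) {
  kind <- match.arg(kind)
  if (is.null(delta))
    delta <- switch(kind, ethanol = -0.4, medium = 0, ascorbate = 0.4)
  if (delta <= -1) stop_invalid("`delta` must be > -1 (T1 cannot reach zero)")
  if (response_tau_min <= 0) stop_invalid("`response_tau_min` must be positive")
  structure(list(kind = kind, delta = delta,
                 response_tau_min = response_tau_min, onset_min = onset_min),
            class = "trigger_spec")
}

#' Instantaneous T1 under a trigger
#'
#' Evaluates the triggered T1 trajectory
#' \eqn{T_1(t) = T_{1,\mathrm{base}}\,(1 + \delta\,(1 - e^{-(t - t_0)/\tau_r}))}
#' for \eqn{t \ge t_0} and the baseline value before onset.
#'
#' @param trigger A [trigger_spec()].
#' @param t1_base_us Baseline T1 in µs.
#' @param t_min Time(s) in minutes (vectorized).
#' @return T1 in µs, same length as `t_min`.
#' @export
t1_at <- function(trigger, t1_base_us, t_min) {
  stopifnot(inherits(trigger, "trigger_spec"))
  if (any(t1_base_us <= 0)) stop_invalid("`t1_base_us` must be positive")
  dt <- pmax(t_min - trigger$onset_min, 0)
  t1_base_us * (1 + trigger$delta * (1 - exp(-dt / trigger$response_tau_min)))
}

#' Expected readout counts for one dark time
#'
#' Mean detected counts in one readout window at dark time `tau_us` and
#' experiment time `t_min`:
#' \deqn{\mu(\tau, t) = [R_b (1 - C (1 - r(\tau, t))) + b(t)]\, w}
#' with relaxation function
#' \eqn{r(\tau,t) = (1 - f)\, e^{-\tau/T_1(t)} + f\, e^{-\tau/t_\mathrm{fast}}},
#' background \eqn{b(t)} from the bleaching model and \eqn{w} the readout
#' window in seconds. `tau_us` and `t_min` are recycled against each other.
#'
#' @param tau_us Dark time(s) in µs.
#' @param t_min Experiment time(s) in minutes.
#' @param phot A [photophysics()].
#' @param bg A [background_model()].
#' @param spec A [pulse_seq_spec()].
#' @return Expected counts per readout (non-negative real).
#' @export
expected_readout_counts <- function(tau_us, t_min, phot, bg, spec) {
  stopifnot(inherits(phot, "photophysics"), inherits(bg, "background_model"),
            inherits(spec, "pulse_seq_spec"))
  t1 <- t1_base_at(phot, t_min)
  r <- (1 - phot$fast_fraction) * exp(-tau_us / t1) +
    phot$fast_fraction * exp(-tau_us / phot$t1_fast_us)
  rate <- phot$bright_rate_cps * (1 - phot$contrast * (1 - r)) + background_at(bg, t_min)
  rate * spec$read_window_us * 1e-6
}

#' Simulate a photon-count sweep block
#'
#' Draws the per-repetition, per-dark-time integrated readout counts of a
#' T1 sweep experiment. Each count is an independent Poisson variate with
#' mean [expected_readout_counts()] evaluated at the repetition's
#' wall-clock time; if a trigger is supplied, the underlying T1 follows
#' [t1_at()]. Counts are drawn by inversion from a seeded uniform stream,
#' so identical `(configuration, seed)` pairs give byte-identical blocks
#' and paired configurations (e.g. the same FND observed through different
#' filters) can be compared with common random numbers.
#'
#' @param phot A [photophysics()].
#' @param bg A [background_model()].
#' @param trigger A [trigger_spec()]; default is the medium control.
#' @param spec A [pulse_seq_spec()].
#' @param n_reps Number of repetitions (rows).
#' @param seed Integer seed (mandatory: simulation is stochastic).
#' @param t0_min Wall-clock time of repetition 0, in minutes.
#' @param meta Optional named list of metadata (particle id, depth_um,
#'   location, age_group, ...).
#' @return An object of class `sweep_block`: list with integer matrix
#'   `counts` (`n_reps` x `n_points`), the `spec`, the ground `truth`
#'   (photophysics, background, trigger, seed, start time) and `meta`.
#' @export
simulate_block <- function(phot, bg, trigger = trigger_spec("medium"),
                           spec = pulse_seq_spec(), n_reps = spec$n_reps_per_curve,
                           seed, t0_min = 0, meta = list()) {
  stopifnot(inherits(phot, "photophysics"), inherits(bg, "background_model"),
            inherits(trigger, "trigger_spec"), inherits(spec, "pulse_seq_spec"))
  if (!is_count(n_reps) || n_reps < 1)
    stop_invalid("`n_reps` must be a positive integer")
  if (missing(seed)) stop_invalid("`seed` is required for simulation")
  taus <- spec$grid$taus_us
  t_min <- t0_min + (seq_len(n_reps) - 1) * spec$sweep_period_s / 60
  t1 <- t1_at(trigger, t1_base_at(phot, t_min), t_min)
  # n_reps x n_points relaxation function, then mean counts
  r <- (1 - phot$fast_fraction) * exp(-outer(1 / t1, taus)) +
    matrix(phot$fast_fraction * exp(-taus / phot$t1_fast_us),
           n_reps, length(taus), byrow = TRUE)
  mu <- phot$bright_rate_cps * (1 - phot$contrast * (1 - r)) +
    background_at(bg, t_min)   # recycles down columns
  mu <- mu * spec$read_window_us * 1e-6
  counts <- with_seed(seed, qpois(runif(length(mu)), as.vector(mu)))
  counts <- matrix(as.integer(counts), n_reps, length(taus))
  structure(list(counts = counts, spec = spec,
                 truth = list(phot = phot, bg = bg, trigger = trigger,
                              seed = seed, t0_min = t0_min),
                 meta = meta),
            class = "sweep_block")
}

#' @export
print.sweep_block <- function(x, ...) {
  cat(sprintf("Sweep block: %d repetitions x %d dark times (%.3g-%.4g us)\n",
              nrow(x$counts), ncol(x$counts),
              x$spec$grid$taus_us[1L], max(x$spec$grid$taus_us)))
  if (length(x$meta)) utils::str(x$meta, give.head = FALSE)
  invisible(x)
}

#' Simulate a measurement cohort
#'
#' Generates the collections of sweep blocks behind the cohort analyses:
#' \describe{
#'   \item{`"locations"`}{`n` particles assigned evenly to 3 areas of the
#'     slice, particle T1s drawn from one shared lognormal distribution
#'     (no true location effect).}
#'   \item{`"depth"`}{`n` particles with depths uniform on
#'     \[0, `depth_max_um`\] and T1 independent of depth (no true slope).}
#'   \item{`"young_old"`}{`n_per_group` particles per age group; the old
#'     group's T1 distribution is scaled down by `old_scale` (higher
#'     radical load).}
#'   \item{`"trigger_panel"`}{`n_per_kind` replicate trigger recordings for
#'     each of ethanol, medium, ascorbate.}
#' }
#' Particle T1s are lognormal with median `t1_median_us` and geometric
#' standard deviation `t1_gsd`.
#'
#' @param scenario One of `"locations"`, `"depth"`, `"young_old"`,
#'   `"trigger_panel"`.
#' @param params Named list of overrides: `n` (42), `n_per_group` (20),
#'   `n_per_kind` (5), `n_reps` (10,000; 165,000 for trigger recordings),
#'   `depth_max_um` (75), `t1_median_us` (200), `t1_gsd` (1.4),
#'   `old_scale` (0.7), `phot`, `bg`, `spec`.
#' @param seed Integer seed.
#' @return List of [simulate_block()] results, each with scenario metadata.
#' @export
simulate_cohort <- function(scenario = c("locations", "depth", "young_old",
                                         "trigger_panel"),
                            params = list(), seed) {
  scenario <- match.arg(scenario)
  if (missing(seed)) stop_invalid("`seed` is required for simulation")
  p <- utils::modifyList(
    list(n = 42L, n_per_group = 20L, n_per_kind = 5L,
         n_reps = NULL, depth_max_um = 75, t1_median_us = 200, t1_gsd = 1.4,
         old_scale = 0.7, phot = photophysics(), bg = background_model(),
         spec = pulse_seq_spec()),
    params)
  draw_t1 <- function(n, median_us, sub) {
    with_seed(derive_seed(seed, sub),
              stats::rlnorm(n, meanlog = log(median_us), sdlog = log(p$t1_gsd)))
  }
  make_block <- function(i, t1, meta, trigger = trigger_spec("medium"), n_reps) {
    phot_i <- p$phot
    phot_i$t1_us <- t1
    simulate_block(phot_i, p$bg, trigger, p$spec, n_reps = n_reps,
                   seed = derive_seed(seed, 1000 + i), meta = meta)
  }
  switch(scenario,
    locations = {
      n_reps <- if (is.null(p$n_reps)) p$spec$n_reps_per_curve else p$n_reps
      t1 <- draw_t1(p$n, p$t1_median_us, 1)
      loc <- rep_len(1:3, p$n)
      lapply(seq_len(p$n), function(i)
        make_block(i, t1[i], list(particle_id = i, location = loc[i],
                                  t1_true_us = t1[i]), n_reps = n_reps))
    },
    depth = {
      n_reps <- if (is.null(p$n_reps)) p$spec$n_reps_per_curve else p$n_reps
      t1 <- draw_t1(p$n, p$t1_median_us, 1)
      depth <- with_seed(derive_seed(seed, 2),
                         stats::runif(p$n, 0, p$depth_max_um))
      lapply(seq_len(p$n), function(i)
        make_block(i, t1[i], list(particle_id = i, depth_um = depth[i],
                                  t1_true_us = t1[i]), n_reps = n_reps))
    },
    young_old = {
      n_reps <- if (is.null(p$n_reps)) p$spec$n_reps_per_curve else p$n_reps
      t1y <- draw_t1(p$n_per_group, p$t1_median_us, 1)
      t1o <- draw_t1(p$n_per_group, p$t1_median_us * p$old_scale, 2)
      c(lapply(seq_len(p$n_per_group), function(i)
          make_block(i, t1y[i], list(particle_id = i, age_group = "young",
                                     t1_true_us = t1y[i]), n_reps = n_reps)),
        lapply(seq_len(p$n_per_group), function(i)
          make_block(p$n_per_group + i, t1o[i],
                     list(particle_id = p$n_per_group + i, age_group = "old",
                          t1_true_us = t1o[i]), n_reps = n_reps)))
    },
    trigger_panel = {
      n_reps <- if (is.null(p$n_reps)) 165000L else p$n_reps
      kinds <- c("ethanol", "medium", "ascorbate")
      t1 <- draw_t1(3 * p$n_per_kind, p$t1_median_us, 1)
      blocks <- vector("list", 3 * p$n_per_kind)
      for (k in seq_along(kinds)) for (j in seq_len(p$n_per_kind)) {
        i <- (k - 1) * p$n_per_kind + j
        blocks[[i]] <- make_block(
          i, t1[i],
          list(particle_id = i, trigger_kind = kinds[k], replicate = j,
               t1_true_us = t1[i]),
          trigger = trigger_spec(kinds[k]), n_reps = n_reps)
      }
      blocks
    })
}
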