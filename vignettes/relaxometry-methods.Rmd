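---
title: "Methods: simulating and analyzing nanodiamond T1 relaxometry"
author: "ndrelax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing nanodiamond T1 relaxometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndrelax)
```

## The measurement

Fluorescent nanodiamonds (FNDs) host nitrogen-vacancy (NV) color centers
whose spin relaxation time T1 is shortened by magnetic noise from nearby
free radicals. A T1 relaxometry recording is a pulsed experiment: a laser
pulse (5 µs) polarizes the NV ensemble into its bright ms = 0 state, the
laser is switched off for a dark time τ, and the next pulse reads out how
much polarization survived — the photon counts integrated over the first
1 µs of the readout pulse. One *repetition* sweeps a log-spaced grid of
dark times (0.2 µs to 2 ms here); summing the readout counts of many
repetitions gives the relaxation curve PL(τ), which decays from the
bright level toward the spin-equilibrium level with time constant T1.

In tissue, the FND signal sits on strong autofluorescence, cells move,
and the radical load evolves when a chemical trigger (ethanol, ascorbic
acid) is added — which is exactly the structure the simulator in this
package reproduces, so that every stage of the analysis can be validated
against known ground truth.

## The photon-count model

`expected_readout_counts()` gives the mean detected counts per readout
window:

$$\mu(\tau, t) = \left[R_b\,\bigl(1 - C\,(1 - r(\tau, t))\bigr) + b(t)\right] w,$$

with

$$r(\tau, t) = (1 - f)\,e^{-\tau/T_1(t)} + f\,e^{-\tau/t_\mathrm{fast}},
\qquad b(t) = b_\infty + (b_0 - b_\infty)\,e^{-t/\tau_\mathrm{bleach}}.$$

* $R_b$ (`bright_rate_cps`, default 2 × 10⁶ counts/s): detected FND rate
  at τ → 0. 120-nm FNDs carry hundreds of NV centers and megacount
  rates through a 650 nm long-pass are realistic for the particles used
  in tissue work. At the 1 µs readout this gives about 2 counts per
  readout and ~2 × 10⁴ summed counts per τ bin in a standard
  10,000-repetition curve.
* $C$ (`contrast`, default 0.3): relative PL drop from full polarization
  to spin equilibrium. A single contrast parameter stands in for the
  ms = ±1 populations; only the shape of PL(τ) matters to the estimator.
* $T_1$ (`t1_us`): the slow relaxation time, the quantity of interest.
  It may be a trajectory (a function of time in minutes), which is how
  trigger-driven drift enters.
* $f, t_\mathrm{fast}$ (`fast_fraction` = 0.2, `t1_fast_us` = 4 µs): a
  fast early decay standing in for short-dark-time photophysics (e.g.
  charge-state dynamics). Real FND relaxation curves show such a
  component — it is the reason the field fits a *double* exponential —
  so the simulator includes one by default.
* $b(t)$: autofluorescence bleaches over minutes (defaults
  $b_0$ = 4 × 10⁵ cps, floor 10⁵ cps, time constant 5 min). The
  background is τ-independent, so within one summation window it only
  shifts the curve's offset and cannot bias T1.
* $w$: the readout window (1 µs).

Counts are independent Poisson variates. They are drawn by *inversion*
(`qpois` applied to a seeded uniform stream) rather than `rpois`: the
distribution is identical, runs are byte-reproducible, and two
configurations simulated from the same seed share common random numbers.
That matters for the filter study, where the same FND is "observed"
through different long-pass filters, exactly as in the paired
experimental design the analysis mirrors. No afterpulsing, detector dead
time, or FND blinking is modeled; shot noise is the only noise source.

One repetition is modeled as `sweep_period_s` = 0.012 s of wall-clock
time. The physical pulses and dark times of the default 21-point grid
only occupy ~2.5 ms (`minimum_sweep_period()`); the rest absorbs
unmodeled hardware overhead. The constant is calibrated so that 10,000
repetitions take exactly 2 minutes, which makes the standard curve a
2-minute acquisition and the 50,000-repetition summation window a
10-minute one. The number of grid points per sweep is not dictated by
the protocol; 21 points is a typical relaxometry grid and fits inside
the calibrated period. Dark times are swept in ascending order.

## Triggers

A trigger multiplies the baseline T1 by
$1 + \delta (1 - e^{-(t - t_0)/\tau_r})$: ethanol drives radical
production in liver tissue ($\delta < 0$), ascorbic acid scavenges
radicals ($\delta > 0$), plain medium is the control ($\delta = 0$).
Magnitudes are not published numerically, so the defaults
($\delta$ = −0.4 / 0 / +0.4, $\tau_r$ = 8 min) are stated placeholders
chosen to reproduce the qualitative response shapes; they are the
simulator's definition of the study conditions, not estimates.

```{r trigger-shape, fig.width = 5, fig.height = 3.2}
t <- seq(0, 33, by = 0.5)
plot(t, t1_at(trigger_spec("ethanol"), 200, t), type = "l", col = 2,
     ylim = c(100, 300), xlab = "time (min)", ylab = expression(T[1] ~ "(µs)"))
lines(t, t1_at(trigger_spec("ascorbate"), 200, t), col = 3)
abline(h = 200, lty = 3)
```

## Fitting T1

`fit_double_exponential()` minimizes the Poisson-weighted residual

$$\sum_j \frac{(\mathrm{PL}_j - m_j)^2}{\max(\mathrm{PL}_j, 1)},
\qquad m_j = c + a_f e^{-\tau_j/t_f} + a_s e^{-\tau_j/t_s},$$

with the Levenberg–Marquardt algorithm (minpack.lm). The weights are the
Poisson variances of the summed counts, floored at 1 to guard empty
bins. Numerical choices:

* Time constants are optimized in log coordinates with the ordering
  built into the parameterization, $t_s = t_f(1 + e^u)$, which removes
  fast/slow label switching. Amplitudes and offset are bounded below by
  zero; time constants are bounded to [0.05 µs, 10,000 µs].
* Starting values come from `initial_params()`: offset from the mean of
  the last two bins, total amplitude from the first bin's excess, slow
  time from the 1/e crossing of the excess interpolated on the log-τ
  axis, fast time at one tenth of it, amplitudes split 20/80.
* Convergence: relative tolerance 10⁻⁸ on the weighted residual, at most
  2000 model evaluations. Failures are reported via `converged = FALSE`,
  never silently. Flat or offset-only curves are rejected as degenerate
  inputs rather than fitted.
* An analytic Jacobian is supplied; on 21-point curves a fit takes a few
  milliseconds, which is what makes the bootstrap and the rolling window
  cheap.

The **reported T1 is the slow component** $t_s$. The protocol literature
fits "a double exponential to extract T1" without naming the component;
since the fast component exists to absorb short-τ photophysics, the slow
one is the spin relaxation time. With the simulator's matched truth this
convention recovers the true T1 (the test suite checks median recovery
within 10% at 50–400 µs).

The test suite also checks the optimizer against an independent
brute-force oracle: a 200 × 200 log-spaced grid over $(t_f, t_s)$ with
the three linear parameters solved analytically by weighted least
squares at every grid point. The optimizer must match or beat the
oracle's residual.

A caveat that matters when comparing *means* of fitted T1: like any
nonlinear least-squares estimator, $\hat t_s$ has a right-skewed
sampling distribution at low signal, so its mean exceeds the true value
by roughly $T_1 \cdot \mathrm{CV}^2$ while the median stays essentially
unbiased. At the default brightness this is negligible for
50,000-repetition windows (CV of a few percent) but reaches a couple of
percent for short integrations of dim scenes. This is why comparisons
across filter settings are run over the standard 50,000-repetition
summation window — the same integration duration for every cutoff.

## Bootstrap confidence intervals

`bootstrap_ci()` attaches a 95% CI by resampling *repetitions* with
replacement within the summation window, rebuilding the curve (a
weighted column sum, so resampling costs almost nothing) and refitting;
the interval is the 2.5/97.5 percentile range of the replicate T1s
(default 200 replicates), and the half-width is also reported as a
percentage of the point estimate, the convention used for instrument
comparisons. Percentile intervals need no curvature or normality
assumptions, which suits a skewed estimator. A CI is flagged unreliable
when more than 20% of replicate fits fail. Empirical coverage at the
default study conditions (200 simulations, true T1 = 200 µs) falls in
the 90–99% band checked by the test suite.

## The rolling window

`rolling_t1()` turns one long recording into a time series of T1 values:
windows of $W$ = 50,000 repetitions (10 min) advanced in steps of
$S$ = 10,000 (2 min), each summed and fitted independently. The number
of windows is $K = \lfloor (N - W)/S \rfloor + 1$. Two conventions were
genuinely open and are fixed as follows:

* **The final window is snapped to the end of the recording.** When
  $N - W$ is not a multiple of $S$ (a 33-minute recording is 165,000
  repetitions), the last regular start would leave the final minutes
  unanalyzed; instead the last window's start becomes $N - W$, so the
  scheme runs "until the summation window reaches the last data" and the
  final window of a 33-minute recording covers minutes 23–33.
* **A window is labeled by its end time** — the latest information time,
  so the first 0–10 min window plots at 10 min. Window extents, not
  point labels, are what the protocol defines; any fixed convention only
  shifts the trace labels rigidly.

For trigger experiments (`run_trigger_experiment()`), a separate
pre-trigger baseline curve (one standard 10,000-repetition acquisition)
is fitted first; particles with baseline T1 below 130 µs are excluded
(`passes_baseline_filter()`, inclusive at the threshold) because a short
baseline indicates high local radical load from stressed or dying
cells. The rolling trace is then divided by the baseline T1
(`normalize_to_baseline()`), with a synthetic reference point at −1 min
marking the baseline itself. Replicate traces are summarized per
timepoint by the median and interquartile range (`summarize_traces()`).

## Filters and SNR

Tissue autofluorescence concentrates in the blue-green; NV⁰ emits at
575–700 nm and NV⁻ at 640–750 nm. The built-in spectral model uses a
0.3/0.7 NV⁰/NV⁻ mixture (uniform and triangular-peaked-at-690 bands) and
an autofluorescence density with 90% of its weight uniform over
450–550 nm plus a 10% exponential red tail (decay length 50 nm). The
published spectra are figure-only, so these shapes are stated
placeholders consistent with the quoted band edges; conclusions drawn
from them are ordering-level (which filter keeps more of what), not
quantitative transmissions. Long-pass filters are ideal steps — no
measured transmission curves are available.

`band_fraction()` integrates a spectrum above a cutoff exactly (the
representation is piecewise linear); `apply_filter()` scales the FND and
background rates by their respective fractions, leaving the spin
contrast untouched; `compute_snr()` is the FND-to-background intensity
ratio. Raising the cutoff from 600 to 700 nm removes background faster
than signal, so SNR increases monotonically — while the *total* signal
drops, widening the bootstrap CI: the precision trade-off reported for
filter choices. `filter_comparison()` assembles the per-cutoff report
(intensities, SNR, T1, CI) over the common 50,000-repetition
integration with common random numbers across cutoffs.

## Cohort statistics

The statistics layer mirrors the analysis applied to fitted T1 values
downstream, delegating the standard machinery to base R (`aov`, `lm`,
`t.test`) and implementing only what base R lacks:

* `anova_holm_sidak()` — ordinary one-way ANOVA across locations, with
  all pairwise comparisons on the pooled mean square and the Holm–Šidák
  step-down adjustment $1 - (1 - p_{(i)})^{m - i + 1}$ (written here:
  `p.adjust` offers Holm but not the Šidák per-step variant).
* `depth_regression()` — OLS of T1 on depth with the slope t-test.
* `ratio_paired_t()` — the ratio paired t-test: a one-sample t-test of
  log(after/before) against zero, effect reported as the geometric mean
  ratio. Invariant to common rescaling; exactly calibrated when the log
  ratios are normal (the test suite checks 5% ± 2% type-I error over
  2000 null panels).
* `two_group_t()` — unpaired comparison (young vs old cohorts), ordinary
  pooled-variance form by default with a Welch option, since the
  protocol names only "unpaired t test". All tests are two-sided.

Degenerate inputs with a well-defined limit (identical groups, constant
ratios) return the limit flagged `degenerate` instead of erroring.

Cohort ground truth: particle T1s are lognormal, median 200 µs,
geometric SD 1.4 (positive support, spread comparable to what baseline
selection leaves), with the old-age group's median scaled by 0.7; depths
are uniform over the reachable ~75 µm; the location and depth scenarios
contain *no* true effect, so their tests double as specificity checks.
None of these distribution parameters are published values.

## What the simulator does and does not show

Passing tests on simulated data demonstrate that the estimator chain —
summation, double-exponential fit, bootstrap, rolling window,
statistics — is correct and calibrated *under the stated model*:
Poisson shot noise, exponential bleaching, exponential trigger
responses, stationary particles. Real recordings add effects the
simulator deliberately omits: particle drift and refocusing gaps,
detector afterpulsing and dead time, FND blinking and charge-state
conversion, non-exponential bleaching, and operator-driven particle
selection. Published per-particle CI half-widths (±29% to ±66%) are
wider than the defaults here produce, consistent with those unmodeled
noise sources; reproducing any specific measured value is out of scope.

## Problem sizes

The validation suite uses the study-scale protocol sizes: standard
curves of 10,000 repetitions on the 21-point grid; 50-seed recovery
studies per T1 level; 200 coverage simulations with 200 bootstrap
replicates; 33-minute (165,000-repetition) trigger recordings in
5-replicate panels with 40 null control panels; 30-seed filter
comparisons over 50,000-repetition windows; 42-particle location/depth
cohorts and 20-per-group age cohorts; and 2000 null runs for t-test
calibration. Unit tests use smaller blocks where only exact arithmetic
or structure is being checked.
```
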