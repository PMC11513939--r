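# ndrelax

Nanodiamond NV-center T1 relaxometry analysis for free-radical sensing in
living tissue — with a faithful photon-count simulator, so every stage of
the pipeline can be validated against known ground truth.

## The problem

Nitrogen-vacancy (NV) centers in fluorescent nanodiamonds (FNDs) are
optically polarized into a bright spin state by laser pulses; the time T1
they take to relax back to equilibrium is shortened by magnetic noise
from nearby free radicals. Measuring T1 of FNDs inside tissue (e.g.
precision-cut liver slices) therefore reads out the local free-radical
load, and following T1 over time reveals the response to triggers such as
ethanol (radical production, T1 drops) or L-ascorbic acid (radical
scavenging, T1 rises).

A recording is a pulse sequence: 5 µs laser pulses separated by
logarithmically increasing dark times τ (0.2 µs – 2 ms), with the photon
counts of the first 1 µs of each readout pulse as the signal. Summing
many repetitions gives the relaxation curve

PL(τ) = c + a_f·exp(−τ/t_fast) + a_s·exp(−τ/t_slow),

fitted by Poisson-weighted bounded least squares; the slow component is
the reported T1. The package implements, and tests end to end:

- **Simulation** (`simulate_block`, `simulate_cohort`): per-repetition
  Poisson readout counts with spin relaxation, bleaching tissue
  autofluorescence, long-pass-filter-dependent rates, and trigger-driven
  T1 drift — with recorded ground truth.
- **Curve building** (`build_curve`): exact summation over repetition
  windows.
- **T1 fitting** (`fit_double_exponential`, `bootstrap_ci`): bounded
  double-exponential fit with an ordering-safe parameterization, plus
  repetition-level bootstrap 95% CIs; `passes_baseline_filter` applies
  the 130 µs baseline selection rule.
- **Rolling window** (`rolling_t1`, `normalize_to_baseline`,
  `summarize_traces`, `run_trigger_experiment`): time-resolved T1 from a
  50,000-repetition window advanced in 10,000-repetition steps (10-minute
  windows every 2 minutes), normalized to a pre-trigger baseline.
- **Filters and SNR** (`band_fraction`, `apply_filter`, `compute_snr`,
  `filter_comparison`): spectral model of NV⁰/NV⁻ emission vs tissue
  autofluorescence across 600/650/700 nm long-pass cutoffs.
- **Cohort statistics** (`anova_holm_sidak`, `depth_regression`,
  `ratio_paired_t`, `two_group_t`): the location/depth/trigger/age-group
  comparisons applied to fitted T1 values.

## Worked example

```r
library(ndrelax)

# one standard 2-minute acquisition (10,000 repetitions), true T1 = 200 us
block <- simulate_block(photophysics(t1_us = 200), background_model(), seed = 7)
fit <- bootstrap_ci(block, n_boot = 200, seed = 8)
fit
#> T1 fit: T1 = 204.4 us (slow); fast 3.3 us; offset 1.749e+04; converged
#>   95% CI [180.8, 230.4] us (+/-12%)
passes_baseline_filter(fit)
#> [1] TRUE
```

The fitted slow component (204.4 µs) recovers the true T1 within the
bootstrap CI; the ±12% half-width quantifies the shot-noise-limited
precision of a 2-minute curve, and the particle passes the 130 µs
baseline rule, so it would qualify for a trigger experiment:

```r
# baseline fit, 33-minute ethanol recording, rolling window, normalization
res <- run_trigger_experiment(trigger = trigger_spec("ethanol"), seed = 42)
res$baseline_fit
#> T1 fit: T1 = 226.5 us (slow); fast 5.12 us; offset 1.747e+04; converged
tail(as.data.frame(res$trace), 4)
#>    time_min    t1_us converged t1_normalized
#> 10       26 123.5348      TRUE     0.5453220
#> 11       28 122.7282      TRUE     0.5417613
#> 12       30 121.1517      TRUE     0.5348024
#> 13       33 128.1132      TRUE     0.5655323
```

Ethanol drives T1 from its 226 µs baseline down to ~0.55 of baseline by
minute 33 — the radical load has risen. The trace rows are the rolling
windows (minutes 0–10 labeled 10, …, 23–33 labeled 33); an ascorbate
trigger ends above 1, and plain medium stays near 1.

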