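Package: ndrelax
Title: Nanodiamond NV-Center T1 Relaxometry for Free-Radical Sensing in Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of nitrogen-vacancy (NV) center T1
    relaxometry recordings from fluorescent nanodiamonds (FNDs) in living
    tissue. Provides a photon-count simulator for pulsed T1 sweep experiments
    (Poisson shot noise, photobleaching autofluorescence, long-pass filter
    effects, trigger-driven T1 drift), relaxation-curve construction by
    repetition-window summation, bounded double-exponential T1 fitting with
    Poisson weighting and nonparametric bootstrap 95% confidence intervals,
    rolling-window time-resolved T1 traces with baseline normalization,
    signal-to-noise analysis across long-pass filter cutoffs, and the
    cohort-level statistics used to compare T1 between tissue locations,
    depths, treatments, and age groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
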