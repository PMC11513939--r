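# On-disk formats: columnar CSV (optionally gzip-compressed, handled
# transparently by R connections) plus a JSON sidecar carrying the pulse
# sequence, ground truth and metadata for provenance.

sidecar_path <- function(path) {
  sub("\\.csv(\\.gz)?$", ".json", path)
}

spec_to_list <- function(spec) {
  list(pulse_len_us = spec$pulse_len_us, read_window_us = spec$read_window_us,
       taus_us = spec$grid$taus_us, n_reps_per_curve = spec$n_reps_per_curve,
       sweep_period_s = spec$sweep_period_s, pulse_energy_nJ = spec$pulse_energy_nJ)
}

spec_from_list <- function(x) {
  taus <- as.numeric(x$taus_us)
  pulse_seq_spec(pulse_len_us = x$pulse_len_us, read_window_us = x$read_window_us,
                 grid = dark_time_grid(length(taus), taus[1L], taus[length(taus)]),
                 n_reps_per_curve = x$n_reps_per_curve,
                 sweep_period_s = x$sweep_period_s,
                 pulse_energy_nJ = x$pulse_energy_nJ)
}

truth_to_list <- function(truth) {
  if (is.null(truth)) return(NULL)
  phot <- truth$phot
  list(phot = list(bright_rate_cps = phot$bright_rate_cps,
                   contrast = phot$contrast,
                   t1_us = if (is.function(phot$t1_us)) NA else phot$t1_us,
                   t1_fast_us = phot$t1_fast_us,
                   fast_fraction = phot$fast_fraction),
       bg = unclass(truth$bg), trigger = unclass(truth$trigger),
       seed = truth$seed, t0_min = truth$t0_min)
}

#' Write a sweep block to CSV + JSON sidecar
#'
#' Counts are stored long-form with columns `rep_index` (0-based),
#' `tau_index` (0-based) and `counts`; the sidecar (same path with a
#' `.json` extension) carries the pulse-sequence spec, simulation ground
#' truth and metadata. A `.csv.gz` path writes gzip-compressed output.
#'
#' @param block A sweep block.
#' @param path Output path ending in `.csv` or `.csv.gz`.
#' @return `path`, invisibly.
#' @export
write_sweep_block <- function(block, path) {
  stopifnot(inherits(block, "sweep_block"))
  n <- nrow(block$counts)
  m <- ncol(block$counts)
  d <- data.frame(rep_index = rep(0:(n - 1), times = m),
                  tau_index = rep(0:(m - 1), each = n),
                  counts = as.vector(block$counts))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  utils::write.csv(d, con, row.names = FALSE)
  close(con)
  jsonlite::write_json(
    list(format = "ndrelax sweep_block v1", spec = spec_to_list(block$spec),
         truth = truth_to_list(block$truth), meta = block$meta),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a sweep block written by [write_sweep_block()]
#'
#' Validates that the counts form a complete non-negative integer
#' repetition-by-dark-time raster consistent with the sidecar's grid;
#' format errors name the offending CSV line.
#'
#' @param path Path to the `.csv` / `.csv.gz` file (sidecar must sit next
#'   to it).
#' @return A `sweep_block`.
#' @export
read_sweep_block <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop_invalid("missing JSON sidecar `%s` for `%s`", sc, path)
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  d <- utils::read.csv(path)
  need <- c("rep_index", "tau_index", "counts")
  if (!all(need %in% names(d)))
    stop_invalid("`%s`: expected columns %s", path, paste(need, collapse = ", "))
  bad <- which(d$counts < 0 | d$counts != floor(d$counts))
  if (length(bad))
    stop_invalid("`%s`: invalid count at line %d (value %s)", path,
                 bad[1L] + 1L, format(d$counts[bad[1L]]))
  spec <- spec_from_list(side$spec)
  m <- spec$grid$n_points
  n <- max(d$rep_index) + 1L
  if (nrow(d) != n * m || max(d$tau_index) + 1L != m)
    stop_invalid("`%s`: ragged raster (%d rows for %d reps x %d dark times)",
                 path, nrow(d), n, m)
  counts <- matrix(NA_integer_, n, m)
  counts[cbind(d$rep_index + 1L, d$tau_index + 1L)] <- as.integer(d$counts)
  if (anyNA(counts))
    stop_invalid("`%s`: incomplete raster (missing rep/tau combinations)", path)
  truth <- side$truth
  if (!is.null(truth)) {
    truth <- list(
      phot = if (!is.null(truth$phot) && !is.na(truth$phot$t1_us[1L]))
        do.call(photophysics, truth$phot) else NULL,
      bg = do.call(background_model, truth$bg),
      trigger = do.call(trigger_spec, truth$trigger),
      seed = truth$seed, t0_min = truth$t0_min)
  }
  structure(list(counts = counts, spec = spec, truth = truth,
                 meta = as.list(side$meta)),
            class = "sweep_block")
}

#' Write a relaxation curve to CSV + JSON sidecar
#'
#' Columns `tau_us`, `pl_counts`, `n_reps`; the sidecar records the
#' summation window and sequence spec.
#'
#' @param curve A [build_curve()] result.
#' @param path Output path ending in `.csv` or `.csv.gz`.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "relaxation_curve"))
  d <- data.frame(tau_us = curve$taus_us, pl_counts = curve$pl_counts,
                  n_reps = curve$n_reps)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  utils::write.csv(d, con, row.names = FALSE)
  close(con)
  jsonlite::write_json(
    list(format = "ndrelax curve v1",
         window = list(start_rep = curve$window$start_rep,
                       end_rep = curve$window$end_rep),
         t_center_min = curve$t_center_min, spec = spec_to_list(curve$spec)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a relaxation curve written by [write_curve()]
#'
#' @param path Path to the `.csv` / `.csv.gz` file.
#' @return A `relaxation_curve`.
#' @export
read_curve <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop_invalid("missing JSON sidecar `%s`", sc)
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  d <- utils::read.csv(path)
  spec <- spec_from_list(side$spec)
  structure(list(taus_us = d$tau_us, pl_counts = d$pl_counts,
                 n_reps = d$n_reps[1L],
                 window = rep_window(side$window$start_rep, side$window$end_rep),
                 t_center_min = side$t_center_min, spec = spec),
            class = "relaxation_curve")
}

#' Write a T1 fit to JSON
#'
#' All parameters, the 95% CI, convergence status, the weighted residual
#' and the window provenance.
#'
#' @param fit A [fit_double_exponential()] / [bootstrap_ci()] result.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_t1_fit <- function(fit, path) {
  stopifnot(inherits(fit, "t1_fit"))
  x <- unclass(fit)
  x$t1_boot <- NULL
  x$window <- if (!is.null(x$window))
    list(start_rep = x$window$start_rep, end_rep = x$window$end_rep)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a T1 fit written by [write_t1_fit()]
#'
#' @param path Path to the `.json` file.
#' @return A `t1_fit`.
#' @export
read_t1_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$window)) x$window <- rep_window(x$window$start_rep, x$window$end_rep)
  for (f in c("ci95_low_us", "ci95_high_us", "ci95_halfwidth_pct"))
    if (is.null(x[[f]])) x[[f]] <- NA_real_
  if (is.null(x$ci_unreliable)) x$ci_unreliable <- NA
  structure(x, class = "t1_fit")
}

#' Write a T1 trace to CSV + JSON sidecar
#'
#' Columns `time_min`, `t1_us`, `converged` and, when present,
#' `t1_normalized`; the sidecar records the rolling-window scheme and the
#' baseline.
#'
#' @param trace A [rolling_t1()] result.
#' @param path Output path ending in `.csv` or `.csv.gz`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "t1_trace"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE)
  close(con)
  jsonlite::write_json(
    list(format = "ndrelax trace v1", window_reps = trace$window_reps,
         step_reps = trace$step_reps, baseline_t1_us = trace$baseline_t1_us),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a T1 trace written by [write_trace()]
#'
#' @param path Path to the `.csv` / `.csv.gz` file.
#' @return A `t1_trace`.
#' @export
read_trace <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop_invalid("missing JSON sidecar `%s`", sc)
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  d <- utils::read.csv(path)
  structure(list(times_min = d$time_min, t1_us = d$t1_us,
                 converged = as.logical(d$converged),
                 normalized = if ("t1_normalized" %in% names(d)) d$t1_normalized,
                 baseline_t1_us = if (is.null(side$baseline_t1_us)) NA_real_
                   else side$baseline_t1_us,
                 window_reps = side$window_reps, step_reps = side$step_reps,
                 windows = NULL),
            class = "t1_trace")
}

#' Read a run configuration from YAML
#'
#' Builds the simulation and analysis objects for a full run from a YAML
#' file with optional blocks `sequence`, `photophysics`, `background`,
#' `trigger`, `rolling` (`window_reps`, `step_reps`), `cutoffs`, and a
#' mandatory integer `seed` (every stochastic stage derives its substream
#' from it).
#'
#' @param path Path to the YAML file.
#' @return List with `spec`, `phot`, `bg`, `trigger`, `rolling`,
#'   `cutoffs`, `seed`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_invalid("the `yaml` package is required to read run configurations")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed) || !is_count(cfg$seed))
    stop_invalid("`%s`: an integer `seed` is mandatory", path)
  seq_cfg <- cfg$sequence
  grid <- if (!is.null(seq_cfg$n_points))
    dark_time_grid(seq_cfg$n_points,
                   seq_cfg$tau_min_us %||% 0.2, seq_cfg$tau_max_us %||% 2000)
  else dark_time_grid()
  spec_args <- seq_cfg[intersect(names(seq_cfg),
                                 c("pulse_len_us", "read_window_us",
                                   "n_reps_per_curve", "sweep_period_s",
                                   "pulse_energy_nJ"))]
  spec <- do.call(pulse_seq_spec, c(spec_args, list(grid = grid)))
  list(spec = spec,
       phot = do.call(photophysics, cfg$photophysics %||% list()),
       bg = do.call(background_model, cfg$background %||% list()),
       trigger = do.call(trigger_spec, cfg$trigger %||% list()),
       rolling = utils::modifyList(list(window_reps = 50000, step_reps = 10000),
                                   cfg$rolling %||% list()),
       cutoffs = cfg$cutoffs %||% c(600, 650, 700),
       seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
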