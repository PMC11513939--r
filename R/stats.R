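#' Holm-Sidak step-down adjustment
#'
#' Step-down multiple-comparison adjustment with Sidak per-step levels:
#' for ordered raw p-values \eqn{p_{(1)} \le \dots \le p_{(m)}} the
#' adjusted value is \eqn{1 - (1 - p_{(i)})^{m - i + 1}}, enforced
#' monotone non-decreasing and capped at 1. Slightly less conservative
#' than plain Holm; it is the procedure paired with ordinary one-way
#' ANOVA in common biostatistics software.
#'
#' @param p Raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_sidak_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_invalid("p-values must be in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

stat_result <- function(method, statistic, p_value, effect, n,
                        comparisons = NULL, degenerate = FALSE) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 effect = effect, n = n, comparisons = comparisons,
                 degenerate = degenerate),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n", x$method, x$statistic,
              x$p_value, if (isTRUE(x$degenerate)) " [degenerate input]" else ""))
  if (!is.null(x$comparisons)) print(x$comparisons)
  invisible(x)
}

#' One-way ANOVA with Holm-Sidak pairwise comparisons
#'
#' Ordinary (fixed-effects, equal-variance) one-way ANOVA across groups of
#' T1 values, followed by all pairwise comparisons using the pooled
#' within-group mean square, adjusted with [holm_sidak_adjust()]. Used to
#' compare T1 between different locations within a tissue slice.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return A `stat_result` with the F statistic, its p-value, and a
#'   `comparisons` data frame (pairwise mean differences, raw and adjusted
#'   p-values).
#' @export
anova_holm_sidak <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop_invalid("`groups` must be a list of at least 2 samples")
  n_i <- lengths(groups)
  if (any(n_i < 2)) stop_invalid("every group needs at least 2 observations")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), n_i), levels = names(groups))
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1L]]
  fstat <- tab[["F value"]][1L]
  pval <- tab[["Pr(>F)"]][1L]
  mse <- tab[["Mean Sq"]][2L]
  df2 <- tab[["Df"]][2L]
  if (!is.finite(fstat)) { # zero between- and within-group variance
    fstat <- 0
    pval <- 1
  }
  means <- vapply(groups, mean, numeric(1))
  pairs <- utils::combn(names(groups), 2)
  diffs <- means[pairs[1L, ]] - means[pairs[2L, ]]
  se <- sqrt(mse * (1 / n_i[pairs[1L, ]] + 1 / n_i[pairs[2L, ]]))
  tt <- ifelse(se > 0, diffs / se, 0)
  praw <- 2 * stats::pt(abs(tt), df2, lower.tail = FALSE)
  comparisons <- data.frame(
    group1 = pairs[1L, ], group2 = pairs[2L, ],
    mean_diff = unname(diffs), t = unname(tt), p_raw = unname(praw),
    p_adjusted = holm_sidak_adjust(unname(praw)),
    row.names = NULL)
  stat_result("one-way ANOVA + Holm-Sidak", fstat, pval,
              effect = means, n = n_i, comparisons = comparisons)
}

#' Linear regression of T1 on measurement depth
#'
#' Ordinary least squares of T1 against depth within the slice, with the
#' t-test of the slope against zero (significance of any depth dependence
#' of the recorded T1).
#'
#' @param t1_us T1 values (µs).
#' @param depth_um Depths (µm), same length, non-constant.
#' @return A `stat_result`; `effect` is the slope (µs per µm),
#'   `statistic` its t value.
#' @export
depth_regression <- function(t1_us, depth_um) {
  if (length(t1_us) != length(depth_um) || length(t1_us) < 3)
    stop_invalid("need matched samples of length >= 3")
  if (stats::var(depth_um) == 0) stop_invalid("depth is constant: slope undefined")
  if (stats::var(t1_us) == 0)  # exactly flat response: slope 0, nothing to test
    return(stat_result("depth regression", 0, 1, effect = 0,
                       n = length(t1_us), degenerate = TRUE))
  fit <- stats::lm(t1_us ~ depth_um)
  sm <- summary(fit)$coefficients
  if (nrow(sm) < 2 || !is.finite(sm[2L, 3L])) {
    # residual variance zero around a flat line: no depth effect
    return(stat_result("depth regression", 0, 1,
                       effect = unname(stats::coef(fit)[2L]),
                       n = length(t1_us), degenerate = TRUE))
  }
  stat_result("depth regression", sm[2L, 3L], sm[2L, 4L],
              effect = sm[2L, 1L], n = length(t1_us))
}

#' Ratio paired t-test
#'
#' Paired comparison of positive measurements on a multiplicative scale:
#' a one-sample t-test of log(after/before) against zero. The effect is
#' the geometric mean ratio after/before; used to compare T1 before and
#' after a trigger. Invariant to a common rescaling of both samples.
#'
#' @param before,after Paired positive samples of equal length (n >= 2).
#' @return A `stat_result`; `effect` is the geometric mean ratio. With a
#'   perfectly constant ratio the log-ratios have zero variance and the
#'   limiting p-value (0 for ratio != 1, 1 for ratio = 1) is returned with
#'   `degenerate = TRUE`.
#' @export
ratio_paired_t <- function(before, after) {
  if (length(before) != length(after) || length(before) < 2)
    stop_invalid("`before` and `after` must have equal length >= 2")
  if (any(before <= 0) || any(after <= 0))
    stop_invalid("ratio paired t-test needs strictly positive values")
  lr <- log(after / before)
  gm <- exp(mean(lr))
  if (stats::sd(lr) == 0) {
    return(stat_result("ratio paired t-test",
                       statistic = if (gm == 1) 0 else sign(mean(lr)) * Inf,
                       p_value = if (gm == 1) 1 else 0,
                       effect = gm, n = length(before), degenerate = TRUE))
  }
  tt <- stats::t.test(lr, mu = 0)
  stat_result("ratio paired t-test", unname(tt$statistic), tt$p.value,
              effect = gm, n = length(before))
}

#' Two-sample t-test on T1 values
#'
#' Unpaired comparison of two groups (for example T1 in liver slices from
#' young versus old mice). The ordinary equal-variance form is the
#' default, with a Welch option.
#'
#' @param a,b Samples (each n >= 2).
#' @param var_equal Use the pooled-variance (ordinary) test; `FALSE` gives
#'   Welch.
#' @return A `stat_result`; `effect` is `mean(a) - mean(b)`.
#' @export
two_group_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    stop_invalid("both groups need at least 2 observations")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    d <- mean(a) - mean(b)
    return(stat_result("two-sample t-test",
                       statistic = if (d == 0) 0 else sign(d) * Inf,
                       p_value = if (d == 0) 1 else 0,
                       effect = d, n = c(length(a), length(b)),
                       degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  stat_result(if (var_equal) "two-sample t-test" else "Welch t-test",
              unname(tt$statistic), tt$p.value,
              effect = mean(a) - mean(b), n = c(length(a), length(b)))
}
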