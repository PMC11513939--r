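# Independent brute-force oracle for the double-exponential fit: a dense
# log-spaced grid over (t_fast, t_slow) with the offset and both amplitudes
# solved analytically by weighted linear least squares at each grid point.
# Uses the same Poisson weighting metric as the fit it checks,
# sum (y - m)^2 / max(y, 1), but shares no code with the optimizer.
grid_search_dexp <- function(taus, y, n_grid = 200, t_range = c(0.05, 1e4)) {
  w <- 1 / pmax(y, 1)
  ts <- exp(seq(log(t_range[1]), log(t_range[2]), length.out = n_grid))
  E <- exp(-outer(taus, 1 / ts))
  wE <- w * E
  sw <- sum(w)
  swy <- sum(w * y)
  syy <- sum(w * y^2)
  s1e <- colSums(wE)
  sey <- colSums(wE * y)
  Cee <- crossprod(E, wE)
  best <- list(resid = Inf, t_fast = NA, t_slow = NA, coef = NULL)
  for (i in seq_len(n_grid)) {
    for (j in i:n_grid) {
      A <- matrix(c(sw, s1e[i], s1e[j],
                    s1e[i], Cee[i, i], Cee[i, j],
                    s1e[j], Cee[i, j], Cee[j, j]), 3L, 3L)
      b <- c(swy, sey[i], sey[j])
      coef <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(coef)) next
      r <- syy - sum(b * coef)  # exact WLS residual at the solution
      if (r < best$resid)
        best <- list(resid = r, t_fast = ts[i], t_slow = ts[j], coef = coef)
    }
  }
  best
}

# Textbook one-way ANOVA F from scratch (closed form, no model fitting).
anova_f_by_hand <- function(groups) {
  n_i <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / sum(n_i)
  msb <- sum(n_i * (means - grand)^2) / (length(groups) - 1)
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) /
    (sum(n_i) - length(groups))
  msb / mse
}
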