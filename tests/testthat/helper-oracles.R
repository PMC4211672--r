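# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct integration, closed forms, brute-force
# enumeration, textbook least squares.

# integral of the piecewise-linear interpolant of (t, y) from t[1] to `upto`,
# by fine-grid trapezoid on the interpolant
oracle_auc_linear <- function(t, y, upto, n_grid = 20001L) {
  grid <- seq(t[1L], upto, length.out = n_grid)
  grid <- sort(unique(c(grid, t[t >= t[1L] & t <= upto])))  # hit the knots
  yy <- approx(t, y, xout = grid)$y
  sum(diff(grid) * (yy[-1L] + yy[-length(yy)]) / 2)
}

# two-sided exact signed-rank p-value by full 2^n enumeration of sign
# assignments (tie-free |d| assumed, zeros already removed)
oracle_wilcox_exact <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  venum <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- if (v > mu) 2 * mean(venum >= v) else 2 * mean(venum <= v)
  min(1, p)
}

# textbook least squares
oracle_ols <- function(X, y) solve(crossprod(X), crossprod(X, y))

# least-squares slope of ln(y) on t (terminal log-linear fit)
oracle_loglin_slope <- function(t, y) {
  X <- cbind(1, t)
  unname(oracle_ols(X, log(y))[2L])
}

make_profile <- function(t, y) pk_profile(t, y)

# random eligible profile generator for property sweeps; optionally forces
# the >24 h interpolation or [22,24) imputation branch
random_profile <- function(branch = c("inside", "interp", "impute")) {
  branch <- match.arg(branch)
  n_mid <- sample(2:6, 1L)
  t_mid <- sort(runif(n_mid, 0.2, 20))
  t_last <- switch(branch,
                   inside = runif(1, 20.2, 21.9),
                   interp = runif(1, 24.05, 26),
                   impute = runif(1, 22, 23.99))
  t <- c(0, t_mid, t_last)
  y <- rlnorm(length(t), meanlog = 2, sdlog = 1)
  pk_profile(t, y)
}
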