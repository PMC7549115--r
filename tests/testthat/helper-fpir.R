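# shared fixtures and independent oracles (kept free of package internals)

sim_quick <- function(...) simulate_fpir_data(fpir_sim_spec(...))

# brute-force normal-equations solve: the independent OLS oracle
normal_eq_fit <- function(X, y) {
  b <- solve(t(X) %*% X, t(X) %*% y)
  r <- y - X %*% b
  rss <- sum(r^2)
  list(coef = drop(b), rss = rss, r2 = 1 - rss / sum((y - mean(y))^2))
}

# brute-force R2 of the fractional-power model at one exponent pair, via lm
brute_r2 <- function(data, m, n) {
  x1 <- data$x[, 1]; x2 <- data$x[, 2]
  z <- x1^m * x2^n
  if (any(!is.finite(z))) return(NA_real_)
  fit <- stats::lm(data$y ~ x1 + x2 + z)
  if (anyNA(stats::coef(fit))) return(NA_real_)   # aliased candidate
  summary(fit)$r.squared
}

# two-sided t tail by direct quadrature of the density formula, independent
# of stats::pt
t_tail_two_sided <- function(tval, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(tval), Inf, rel.tol = 1e-10)$value
}

# random well-conditioned design for engine tests
random_design <- function(n, k, seed) {
  set.seed(seed)
  X <- cbind(1, matrix(stats::rnorm(n * (k - 1)), n))
  colnames(X) <- c("(Intercept)", paste0("Z", seq_len(k - 1)))
  list(X = X, y = stats::rnorm(n))
}

expect_rel_equal <- function(got, want, tol = 1e-8) {
  expect_lt(max(abs(got - want) / pmax(abs(want), 1)), tol)
}
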