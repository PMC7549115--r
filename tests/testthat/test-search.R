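test_that("interaction column reduces to the product at (1, 1) and flags domain violations", {
  x1 <- c(0, 0.5, 1); x2 <- c(0.2, 0.4, 0.8)
  ic <- interaction_column(x1, x2, 1, 1)
  expect_true(ic$valid)
  expect_equal(ic$column, x1 * x2)
  # zero base with a negative exponent is invalid, not an error
  expect_false(interaction_column(x1, x2, -2, 1)$valid)
  # constant-ones candidate is valid here; collinearity is the rank check's job
  expect_true(interaction_column(rep(1, 3), rep(1, 3), 5, -3)$valid)
})

test_that("R2 surface is exact on a constructed y = x1^2 * x2 fixture", {
  set.seed(1)
  x1 <- runif(60, 0.1, 1); x2 <- runif(60, 0.1, 1)
  d <- fpir_data(x1^2 * x2, cbind(X1 = x1, X2 = x2))
  s <- r2_surface(d, c(1, 2, 3), c(0.5, 1, 2))
  expect_equal(s["2", "1"], 1, tolerance = 1e-10)
  expect_equal(which(unclass(s) == max(s), arr.ind = TRUE)[1, ],
               c(row = 2, col = 2))
  # the (1, 1) cell is the regular-regression R2 by definition
  expect_equal(s["1", "1"], fit_regular(d)$r2, tolerance = 1e-10)
})

test_that("two-stage search recovers generative exponents and dominates the regular fit", {
  d <- sim_quick(seed = 42)   # defaults: (M, N) = (4.9, 2.6), n = 500
  fit <- fit_fpir_twoway(d)
  step <- 7 / 9
  expect_lte(abs(fit$m_hat - 4.9), step)
  expect_lte(abs(fit$n_hat - 2.6), step)
  expect_gte(fit$best_fit$r2, fit$baseline_fit$r2)
  expect_equal(fit$best_fit$r2, max(fit$candidate_table$r2, na.rm = TRUE),
               tolerance = 1e-10)
  expect_identical(sum(fit$candidate_table$stage == "initial"), 3025L)
  expect_identical(sum(fit$candidate_table$stage == "tuned"), 100L)
  expect_true(fit$interaction_share >= 0 && fit$interaction_share <= 1)
})

test_that("the search is deterministic", {
  d <- sim_quick(n = 120, seed = 8)
  f1 <- fit_fpir_twoway(d)
  f2 <- fit_fpir_twoway(d)
  expect_identical(f1$candidate_table, f2$candidate_table)
  expect_identical(f1$exponents, f2$exponents)
})

test_that("stage-1 scoring agrees with an exhaustive brute-force lm loop", {
  grid <- seq(-2.5, 2.5, by = 0.5)    # reduced 11 x 11 grid
  for (seed in c(51, 52)) {
    d <- sim_quick(n = 80, m_true = 2, n_true = 1, noise_sd = 0.1, seed = seed)
    s <- r2_surface(d, grid, grid)
    brute <- outer(seq_along(grid), seq_along(grid),
                   Vectorize(function(i, j) brute_r2(d, grid[i], grid[j])))
    expect_equal(unclass(s), brute, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(which.max(unclass(s)), which.max(brute))
  }
})

test_that("simple slope matches the analytic form and a finite difference", {
  # noiseless classical data: the search must settle on (1, 1) and the slope
  # reduces to b1 + b3 * x2
  set.seed(3)
  x1 <- runif(80, 0.1, 1); x2 <- runif(80, 0.1, 1)
  d <- fpir_data(0.5 + 2 * x1 + 3 * x2 + 4 * x1 * x2, cbind(X1 = x1, X2 = x2))
  fit <- fit_fpir_twoway(d)
  expect_equal(unname(fit$exponents), c(1, 1))
  expect_equal(interaction_slope(fit, x1, x2), 2 + 4 * x2, tolerance = 1e-6)

  # fractional fit: slope equals the centred finite difference of the fitted
  # mean surface at 5 probe points
  fit2 <- fit_fpir_twoway(sim_quick(seed = 42))
  b <- fit2$best_fit$coefficients
  mu <- function(x1, x2) {
    b[[1]] + b[[2]] * x1 + b[[3]] * x2 +
      b[[4]] * x1^fit2$m_hat * x2^fit2$n_hat
  }
  p1 <- c(0.2, 0.4, 0.5, 0.7, 0.9); p2 <- c(0.3, 0.9, 0.5, 0.2, 0.8)
  h <- 1e-6
  fd <- (mu(p1 + h, p2) - mu(p1 - h, p2)) / (2 * h)
  expect_equal(interaction_slope(fit2, p1, p2), fd, tolerance = 1e-4)

  # domain guard when the fitted M is below 1
  low_m <- fit2
  low_m$m_hat <- 0.5
  expect_error(interaction_slope(low_m, c(0, 0.5), c(0.5, 0.5)), "domain")
})

test_that("three-way search recovers exponents and contains the classical model", {
  d <- simulate_fpir_data(fpir_sim_spec(
    n = 800, beta = c(0.25, 0.1, 0.9, 0.4, 9.8),
    m_true = 2, n_true = 1, k_true = 3, noise_sd = 0.01, seed = 7))
  fit <- fit_fpir_threeway(d)
  step <- 7 / 9
  expect_lte(abs(fit$m_hat - 2), step)
  expect_lte(abs(fit$n_hat - 1), step)
  expect_lte(abs(fit$k_hat - 3), step)
  expect_gte(fit$best_fit$r2, fit$baseline_fit$r2)
  expect_identical(sum(fit$candidate_table$stage == "initial"), 29791L)
  expect_identical(sum(fit$candidate_table$stage == "tuned"), 1000L)

  # all true exponents 1: searched fit within 0.02 of the regular product model
  d1 <- simulate_fpir_data(fpir_sim_spec(
    n = 400, beta = c(0.25, 0.1, 0.9, 0.4, 4), m_true = 1, n_true = 1,
    k_true = 1, noise_sd = 0.05, seed = 17))
  f1 <- fit_fpir_threeway(d1)
  expect_lte(f1$best_fit$r2 - f1$baseline_fit$r2, 0.02)
})

test_that("three-way null interaction keeps the interaction share small", {
  shares <- vapply(1:20, function(r) {
    d <- simulate_fpir_data(fpir_sim_spec(
      n = 1000, beta = c(0.25, 0.1, 0.9, 0.4, 0), m_true = 1, n_true = 1,
      k_true = 1, noise_sd = 0.1, seed = 600 + r))
    fit_fpir_threeway(d)$interaction_share
  }, numeric(1))
  expect_lt(mean(shares), 0.05)
})
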