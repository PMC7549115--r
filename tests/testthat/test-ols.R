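test_that("coefficients, RSS and R2 match the normal-equations oracle on random designs", {
  for (i in 1:20) {
    n <- sample(10:50, 1)
    k <- sample(2:6, 1)
    prob <- random_design(n, k, seed = 1000 + i)
    fit <- ols_fit(prob$X, prob$y)
    oracle <- normal_eq_fit(prob$X, prob$y)
    expect_rel_equal(unname(fit$coefficients), oracle$coef)
    expect_rel_equal(fit$rss, oracle$rss)
    expect_rel_equal(fit$r2, oracle$r2)
    expect_identical(fit$residual_df, n - k)
  }
})

test_that("noiseless linear data is reproduced exactly", {
  set.seed(4)
  x <- runif(30)
  X <- cbind("(Intercept)" = 1, X1 = x)
  fit <- ols_fit(X, 2 + 3 * x)
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-10)
  expect_lt(fit$rss, 1e-20)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("AIC follows the Gaussian closed form and the searched-exponent penalty", {
  prob <- random_design(20, 3, seed = 77)
  fit <- ols_fit(prob$X, prob$y, n_searched_exponents = 2)
  n <- 20; k <- 3
  expect_equal(fit$aic_naive, n * log(2 * pi * fit$rss / n) + n + 2 * (k + 1),
               tolerance = 1e-12)
  expect_equal(fit$aic_adjusted, fit$aic_naive + 4, tolerance = 1e-12)
  # same convention as the standard lm likelihood AIC
  lmfit <- stats::lm(prob$y ~ prob$X - 1)
  expect_equal(fit$aic_naive, stats::AIC(lmfit), tolerance = 1e-8)
})

test_that("standard errors and p-values follow the t distribution", {
  for (seed in c(11, 12, 13)) {
    prob <- random_design(25, 4, seed = seed)
    fit <- ols_fit(prob$X, prob$y)
    sm <- summary(stats::lm(prob$y ~ prob$X - 1))$coefficients
    expect_equal(unname(fit$std_errors), unname(sm[, 2]), tolerance = 1e-8)
    # p-values against direct quadrature of the t density
    for (j in seq_along(fit$t_stats)) {
      expect_equal(fit$p_values[[j]],
                   t_tail_two_sided(fit$t_stats[[j]], fit$residual_df),
                   tolerance = 1e-7)
    }
  }
})

test_that("sequential SS matches nested-model RSS differences and conserves TSS", {
  d <- sim_quick(n = 60, m_true = 2, n_true = 1, noise_sd = 0.1, seed = 9)
  terms <- list(
    term_spec("(Intercept)"),
    term_spec("X1", c(X1 = 1)),
    term_spec("X2", c(X2 = 1)),
    term_spec("X1.X2", c(X1 = 1, X2 = 1))
  )
  fit <- ols_fit(build_design(d, terms), d$y)
  # nested oracle: explicit lm fits of the growing models
  x1 <- d$x[, 1]; x2 <- d$x[, 2]
  rss_of <- function(f) sum(stats::resid(f)^2)
  r1 <- rss_of(stats::lm(d$y ~ 1))
  r2_ <- rss_of(stats::lm(d$y ~ x1))
  r3 <- rss_of(stats::lm(d$y ~ x1 + x2))
  r4 <- rss_of(stats::lm(d$y ~ x1 + x2 + I(x1 * x2)))
  expect_equal(unname(fit$seq_ss), c(r1 - r1, r1 - r2_, r2_ - r3, r3 - r4),
               tolerance = 1e-8)
  expect_equal(sum(fit$seq_ss) + fit$rss, fit$tss, tolerance = 1e-8 * fit$tss)
  expect_true(all(fit$seq_ss >= -1e-10))
  # the exported helper agrees with the engine
  expect_equal(sequential_ss(d, terms), fit$seq_ss)
})

test_that("sequential SS is order-invariant for orthogonal centered predictors", {
  set.seed(21)
  x1 <- rep(c(-1, 1), each = 20)
  x2 <- rep(c(-1, 1), times = 20)          # orthogonal to x1 and the intercept
  d <- fpir_data(rnorm(40) + x1 - 2 * x2, cbind(A = x1 + 2, B = x2 + 2))
  # centered columns supplied directly as the design
  X12 <- cbind("(Intercept)" = 1, A = x1, B = x2)
  X21 <- X12[, c(1, 3, 2)]
  f12 <- ols_fit(X12, d$y)
  f21 <- ols_fit(X21, d$y)
  expect_equal(f12$seq_ss[c("A", "B")], f21$seq_ss[c("A", "B")],
               tolerance = 1e-10)
})

test_that("adding a column never increases the RSS", {
  for (i in 1:20) {
    prob <- random_design(30, 4, seed = 300 + i)
    set.seed(400 + i)
    extra <- cbind(prob$X, E = rnorm(30))
    expect_lte(ols_fit(extra, prob$y)$rss, ols_fit(prob$X, prob$y)$rss + 1e-12)
  }
})

test_that("rank deficiency and insufficient data raise informative errors", {
  set.seed(5)
  x <- runif(20)
  X <- cbind("(Intercept)" = 1, X1 = x, Twice = 2 * x)
  expect_error(ols_fit(X, rnorm(20)), "collinear.*Twice|Twice.*collinear")
  expect_error(ols_fit(cbind(1, matrix(rnorm(12), 3)), rnorm(3)),
               "insufficient data")
  # scale invariance: a numerically huge but independent column is accepted
  Xbig <- cbind("(Intercept)" = 1, X1 = x, Big = exp(40 * x))
  expect_s3_class(ols_fit(Xbig, rnorm(20)), "ols_fit")
})

test_that("design builder evaluates term specs and flags invalid entries", {
  d <- fpir_data(1:5, cbind(X1 = c(0, 1, 2, 3, 4), X2 = c(1, 2, 3, 4, 5)))
  X <- build_design(d, list(term_spec("(Intercept)")))
  expect_equal(unname(X[, 1]), rep(1, 5))
  X <- build_design(d, list(term_spec("prod", c(X1 = 1, X2 = 1))))
  expect_equal(unname(X[, 1]), d$x[, 1] * d$x[, 2])
  dpos <- fpir_data(1:5, cbind(X1 = 1:5 / 5, X2 = 1:5 / 5))
  X <- build_design(dpos, list(term_spec("zero", c(X1 = 0, X2 = 0))))
  expect_equal(unname(X[, 1]), rep(1, 5))
  expect_true(attr(X, "valid"))
  # 0 to a negative power: flagged, not an error
  X <- build_design(d, list(term_spec("bad", c(X1 = -2))))
  expect_false(attr(X, "valid"))
  expect_error(build_design(d, list(term_spec("oops", c(Nope = 1)))),
               "unknown predictor.*Nope")
})

test_that("incomplete rows are dropped and counted at construction", {
  d <- fpir_data(c(1, NA, 3, 4), cbind(X1 = c(1, 2, NA, 4), X2 = 1:4))
  expect_equal(d$n, 2)
  expect_equal(d$dropped, 2)
})
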