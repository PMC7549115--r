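#' Ordinary least squares with sequential sums of squares
#'
#' Fits a linear model by QR decomposition and returns every per-model
#' statistic the package reports: coefficients with standard errors and
#' t-based p-values, residual and total sums of squares, R-squared and
#' adjusted R-squared, residual degrees of freedom, the sequential (Type I)
#' sum of squares of each term in the declared column order, and two AIC
#' variants.
#'
#' AIC is computed under the Gaussian likelihood as
#' `n*log(2*pi*rss/n) + n + 2*(p + 1)` where `p` parameters are counted plus
#' one for the residual variance. `aic_naive` counts only the `k` linear
#' coefficients (`p = k`); `aic_adjusted` additionally counts exponents that
#' were estimated by grid search (`p = k + n_searched_exponents`), making the
#' selection penalty explicit when fractional exponents were data-driven.
#'
#' @param design Numeric design matrix (n x k), finite, full column rank.
#' @param y Numeric response vector, length n > k.
#' @param n_searched_exponents Number of exponents selected by grid search
#'   before this fit (0 for models with fixed functional form).
#' @return An object of class `ols_fit`.
#' @examples
#' x <- runif(40); X <- cbind("(Intercept)" = 1, X1 = x)
#' fit <- ols_fit(X, 2 + 3 * x)
#' fit$coefficients
#' @export
ols_fit <- function(design, y, n_searched_exponents = 0) {
  X <- as.matrix(design)
  y <- as.numeric(y)
  n <- length(y)
  k <- ncol(X)
  if (nrow(X) != n) stop("design and response lengths differ", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("design and response must be finite", call. = FALSE)
  }
  if (n <= k) {
    stop("insufficient data: n = ", n, " observations for ", k, " coefficients",
         call. = FALSE)
  }
  term_names <- colnames(X)
  if (is.null(term_names)) term_names <- paste0("V", seq_len(k))

  # compute on unit-norm columns so the rank check and the factorization are
  # invariant to column scaling (fractional-power columns can differ by
  # dozens of orders of magnitude); coefficients are unscaled afterwards
  scale_ <- sqrt(colSums(X^2))
  if (any(scale_ == 0)) {
    stop("singular model: term(s) collinear with earlier terms: ",
         paste(term_names[scale_ == 0], collapse = ", "), call. = FALSE)
  }
  Xs <- sweep(X, 2, scale_, "/")

  # rank check: relative singular value below 1e-10 counts as deficient
  sv <- svd(Xs, nu = 0, nv = 0)$d
  if (k > 1 && min(sv) < 1e-10 * max(sv)) {
    qx <- qr(Xs, tol = 1e-10)
    bad <- if (qx$rank < k) term_names[qx$pivot[seq(qx$rank + 1, k)]]
           else term_names[k]
    stop("singular model: term(s) collinear with earlier terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  qx <- qr(Xs)
  coef <- qr.coef(qx, y) / scale_
  res <- qr.resid(qx, y)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df <- n - k
  sigma2 <- rss / df
  xtx_inv <- chol2inv(chol(crossprod(Xs)))
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2) / scale_
  tval <- coef / se
  pval <- 2 * stats::pt(-abs(tval), df)

  # sequential (Type I) SS: RSS drop when each term joins the model that
  # already holds all preceding terms, in declared order
  has_intercept <- all(X[, 1] == 1)
  rss_prev <- if (has_intercept) tss else sum(y^2)
  seq_ss <- numeric(k)
  for (j in seq_len(k)) {
    rss_j <- if (j == k) rss else
      sum(stats::.lm.fit(Xs[, seq_len(j), drop = FALSE], y)$residuals^2)
    seq_ss[j] <- rss_prev - rss_j
    rss_prev <- rss_j
  }

  r2 <- 1 - rss / tss
  aic_naive <- n * log(2 * pi * rss / n) + n + 2 * (k + 1)

  structure(list(
    coefficients = stats::setNames(coef, term_names),
    std_errors = stats::setNames(se, term_names),
    t_stats = stats::setNames(tval, term_names),
    p_values = stats::setNames(pval, term_names),
    rss = rss, tss = tss,
    r2 = r2,
    adj_r2 = 1 - (1 - r2) * (n - 1) / df,
    residual_df = df,
    seq_ss = stats::setNames(seq_ss, term_names),
    aic_naive = aic_naive,
    aic_adjusted = aic_naive + 2 * n_searched_exponents,
    n_searched_exponents = n_searched_exponents,
    n = n,
    fitted = as.numeric(y - res),
    term_names = term_names
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, digits = 4, ...) {
  cat("Ordinary least squares fit (n = ", x$n, ")\n\n", sep = "")
  tab <- data.frame(
    Estimate = x$coefficients,
    `Std. Error` = x$std_errors,
    `t value` = x$t_stats,
    `Pr(>|t|)` = x$p_values,
    `Seq SS` = x$seq_ss,
    check.names = FALSE
  )
  print(round(tab, digits))
  cat(sprintf("\nRSS %.4g on %d df;  R2 %.4f (adj. %.4f)\n",
              x$rss, x$residual_df, x$r2, x$adj_r2))
  cat(sprintf("AIC %.2f (naive), %.2f (counting %d searched exponents)\n",
              x$aic_naive, x$aic_adjusted, x$n_searched_exponents))
  invisible(x)
}

#' Sequential sum-of-squares decomposition
#'
#' Convenience wrapper: builds the design for an ordered term list and
#' returns the per-term sequential (Type I) sums of squares. The SS of term
#' j is the residual-SS reduction when term j is added to the model holding
#' terms 1..j-1; summed over non-intercept terms with the final RSS it
#' reconstructs the total SS.
#'
#' @inheritParams build_design
#' @return Named numeric vector of per-term sums of squares.
#' @export
sequential_ss <- function(data, terms) {
  X <- build_design(data, terms)
  if (!attr(X, "valid")) stop("design contains non-finite entries", call. = FALSE)
  ols_fit(X, data$y)$seq_ss
}
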