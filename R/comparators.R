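#' Regular interaction regression
#'
#' The classical multiple regression with a product interaction term,
#' `Y ~ b0 + b1*X1 + b2*X2 + b3*X1*X2 + e` — the special case of the
#' fractional-power model with both exponents fixed at 1.
#'
#' @inheritParams fit_fpir_twoway
#' @return An [ols_fit] object.
#' @export
fit_regular <- function(data) {
  stopifnot(inherits(data, "fpir_data"))
  if (ncol(data$x) != 2) stop("exactly 2 predictors required", call. = FALSE)
  preds <- colnames(data$x)
  terms <- c(main_effect_terms(preds), list(interaction_term(preds, c(1, 1))))
  ols_fit(build_design(data, terms), data$y)
}

#' Bivariate polynomial regression
#'
#' Full polynomial basis of total degree at most `order` in the two
#' predictors: every monomial `X1^a * X2^b` with `a + b <= order`, i.e.
#' `(order+1)(order+2)/2` terms including the intercept (15 at the default
#' order 4). Terms are ordered by total degree, and within a degree by
#' descending power of the first predictor.
#'
#' @inheritParams fit_fpir_twoway
#' @param order Maximum total degree (default 4).
#' @return An [ols_fit] object.
#' @export
fit_polynomial <- function(data, order = 4) {
  stopifnot(inherits(data, "fpir_data"))
  if (ncol(data$x) != 2) stop("exactly 2 predictors required", call. = FALSE)
  stopifnot(order >= 1)
  preds <- colnames(data$x)
  terms <- list(term_spec("(Intercept)"))
  for (d in seq_len(order)) {
    for (a in d:0) {
      b <- d - a
      e <- c(a, b)[c(a, b) > 0]
      nm <- paste(sprintf("%s^%d", preds[c(a, b) > 0], e), collapse = ".")
      terms <- c(terms, list(term_spec(nm, stats::setNames(e, preds[c(a, b) > 0]))))
    }
  }
  ols_fit(build_design(data, terms), data$y)
}

#' Fractional-power interaction regression with quadratic terms
#'
#' The quadratic-augmented variant: the two-stage exponent search is rerun
#' with `X1^2` and `X2^2` present in every candidate model,
#' `Y ~ b0 + b1*X1 + b2*X2 + b3*X1^M*X2^N + b4*X1^2 + b5*X2^2 + e`.
#' Because each candidate nests the corresponding plain fractional-power
#' candidate, the selected model's R-squared can never fall below the plain
#' search's.
#'
#' @inheritParams fit_fpir_twoway
#' @return An `fpir_fit` object (see [fit_fpir_twoway()]); its
#'   `baseline_fit` is the same model with both exponents fixed at 1.
#' @export
fit_fpirp <- function(data) search_twoway(data, quadratics = TRUE)

#' Side-by-side model comparison
#'
#' Fits the regular interaction regression, the fractional-power search, its
#' quadratic-augmented variant, and the bivariate polynomial regression on
#' the same data, and assembles a comparison report: one summary row per
#' model (R-squared, adjusted R-squared, both AIC conventions, residual df,
#' term count) plus per-term detail (coefficient, SE, p-value, sequential
#' SS) for the regular and fractional-power fits.
#'
#' @inheritParams fit_polynomial
#' @return An object of class `fpir_comparison` with elements `summary`
#'   (data frame), `detail` (named list of per-term data frames) and `fits`
#'   (the underlying fit objects).
#' @export
compare_models <- function(data, order = 4) {
  regular <- fit_regular(data)
  fpir <- fit_fpir_twoway(data)
  fpirp <- fit_fpirp(data)
  poly <- fit_polynomial(data, order = order)

  row_of <- function(label, fit) {
    data.frame(model = label, r2 = fit$r2, adj_r2 = fit$adj_r2,
               aic_naive = fit$aic_naive, aic_adjusted = fit$aic_adjusted,
               residual_df = fit$residual_df,
               n_terms = length(fit$coefficients),
               stringsAsFactors = FALSE)
  }
  summary <- rbind(
    row_of("regular", regular),
    row_of("fpir", fpir$best_fit),
    row_of("fpirp", fpirp$best_fit),
    row_of(sprintf("polynomial%d", order), poly)
  )

  detail_of <- function(fit) {
    data.frame(term = fit$term_names,
               coefficient = unname(fit$coefficients),
               std_error = unname(fit$std_errors),
               p_value = unname(fit$p_values),
               seq_ss = unname(fit$seq_ss),
               stringsAsFactors = FALSE)
  }

  structure(list(
    summary = summary,
    detail = list(regular = detail_of(regular), fpir = detail_of(fpir$best_fit)),
    exponents = fpir$exponents,
    fits = list(regular = regular, fpir = fpir, fpirp = fpirp, polynomial = poly),
    n = data$n
  ), class = "fpir_comparison")
}

#' @export
print.fpir_comparison <- function(x, digits = 4, ...) {
  cat("Model comparison (n = ", x$n, ")\n\n", sep = "")
  s <- x$summary
  s[-1] <- lapply(s[-1], function(v) round(v, digits))
  print(s, row.names = FALSE)
  for (lab in names(x$detail)) {
    cat("\nPer-term detail —", lab, "\n")
    d <- x$detail[[lab]]
    d[-1] <- lapply(d[-1], function(v) round(v, digits))
    print(d, row.names = FALSE)
  }
  cat(sprintf("\nSelected exponents: M = %.4g, N = %.4g\n",
              x$exponents[["M"]], x$exponents[["N"]]))
  invisible(x)
}
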