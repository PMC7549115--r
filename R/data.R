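#' Assemble a regression dataset
#'
#' Bundles a continuous response with two (or three) continuous predictor
#' columns. Rows containing any missing value are dropped (listwise deletion)
#' and the number of dropped rows is recorded, so the sample size entering
#' every downstream degrees-of-freedom computation is deterministic.
#'
#' @param y Numeric response vector.
#' @param x Numeric matrix or data frame of predictors with column names.
#' @return An object of class `fpir_data`: a list with elements `y` (numeric
#'   vector), `x` (numeric matrix with named columns), `n` (rows retained)
#'   and `dropped` (rows removed because of missing values).
#' @examples
#' d <- fpir_data(rnorm(10), cbind(X1 = runif(10), X2 = runif(10)))
#' d$n
#' @export
fpir_data <- function(y, x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix or data frame of predictors", call. = FALSE)
  }
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    stop("predictor columns must have unique names", call. = FALSE)
  }
  y <- as.numeric(y)
  if (length(y) != nrow(x)) {
    stop("`y` and `x` must have the same number of rows", call. = FALSE)
  }
  keep <- stats::complete.cases(y, x)
  dropped <- sum(!keep)
  y <- y[keep]
  x <- x[keep, , drop = FALSE]
  structure(
    list(y = y, x = x, n = length(y), dropped = dropped),
    class = "fpir_data"
  )
}

#' @export
print.fpir_data <- function(x, ...) {
  cat("<fpir_data> ", x$n, " rows, predictors: ",
      paste(colnames(x$x), collapse = ", "), sep = "")
  if (x$dropped > 0) cat(" (", x$dropped, " incomplete rows dropped)", sep = "")
  cat("\n")
  invisible(x)
}

#' Describe one model term
#'
#' A term is the elementwise product of `predictor^exponent` over a named
#' exponent map; an empty map is the intercept. An ordered list of terms
#' defines a model, intercept first.
#'
#' @param name Term label used in printed output.
#' @param exponents Named numeric vector mapping predictor names to real
#'   exponents; omit (or pass an empty vector) for the intercept.
#' @return An object of class `fpir_term`.
#' @examples
#' term_spec("Interaction", c(X1 = 4.9, X2 = 2.6))
#' @export
term_spec <- function(name, exponents = numeric(0)) {
  exponents <- unlist(exponents)
  if (length(exponents) && (is.null(names(exponents)) || any(!nzchar(names(exponents))))) {
    stop("`exponents` must be a named vector", call. = FALSE)
  }
  structure(list(name = name, exponents = exponents), class = "fpir_term")
}

# standard term lists -------------------------------------------------------

main_effect_terms <- function(preds) {
  c(list(term_spec("(Intercept)")),
    lapply(preds, function(p) term_spec(p, stats::setNames(1, p))))
}

interaction_term <- function(preds, exponents) {
  term_spec(paste0("Interaction(",
                   paste(sprintf("%s^%g", preds, exponents), collapse = " "), ")"),
            stats::setNames(exponents, preds))
}

#' Build a design matrix from term specifications
#'
#' Evaluates each term of an ordered term list on the data. Non-finite
#' entries (e.g. 0 raised to a negative exponent) do not raise an error;
#' the result carries a `valid` attribute set to `FALSE` so that a grid
#' search can skip the candidate.
#'
#' @param data An [fpir_data] object.
#' @param terms List of [term_spec] objects, intercept first.
#' @return Numeric matrix (n rows, one column per term) with a logical
#'   `valid` attribute.
#' @export
build_design <- function(data, terms) {
  stopifnot(inherits(data, "fpir_data"))
  if (inherits(terms, "fpir_term")) terms <- list(terms)
  cols <- lapply(terms, function(tm) {
    if (!length(tm$exponents)) return(rep(1, data$n))
    unknown <- setdiff(names(tm$exponents), colnames(data$x))
    if (length(unknown)) {
      stop("unknown predictor(s) in term '", tm$name, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    col <- rep(1, data$n)
    for (p in names(tm$exponents)) col <- col * data$x[, p]^tm$exponents[[p]]
    col
  })
  X <- do.call(cbind, cols)
  colnames(X) <- vapply(terms, `[[`, "", "name")
  attr(X, "valid") <- all(is.finite(X))
  X
}
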