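#' Variable transforms
#'
#' Two transforms cover the usual preprocessing for right-skewed,
#' arbitrarily scaled covariates: `log1p` spreads out distributions
#' concentrated at small values (`log(x + 1)`, so 0 maps to 0), and
#' `standardize01` rescales a column linearly so its minimum maps to 0 and
#' its maximum to 1, which puts predictors on the non-negative 0-1 scale the
#' exponent search expects and makes coefficients comparable across
#' variables.
#'
#' @param v Numeric vector.
#' @return Transformed vector; `transform_standardize01` carries the
#'   min/max used as attribute `"range"` so new data can be transformed
#'   identically.
#' @name transforms
NULL

#' @rdname transforms
#' @export
transform_log1p <- function(v) {
  if (any(v <= -1, na.rm = TRUE)) {
    stop("log1p transform requires values > -1", call. = FALSE)
  }
  log1p(v)
}

#' @rdname transforms
#' @export
transform_standardize01 <- function(v) {
  rng <- range(v, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    stop("standardize01 transform: column is constant (zero range)",
         call. = FALSE)
  }
  out <- (v - rng[1]) / (rng[2] - rng[1])
  attr(out, "range") <- rng
  out
}

apply_transform <- function(v, kind, col) {
  meta <- list(column = col, transform = kind)
  out <- switch(kind,
    none = v,
    log1p = transform_log1p(v),
    standardize01 = transform_standardize01(v),
    both = transform_standardize01(transform_log1p(v)),
    stop("unknown transform '", kind, "' for column '", col,
         "' (use none, log1p, standardize01 or both)", call. = FALSE)
  )
  if (!is.null(attr(out, "range"))) {
    meta$min <- attr(out, "range")[1]
    meta$max <- attr(out, "range")[2]
    attr(out, "range") <- NULL
  }
  list(values = out, meta = meta)
}

#' Load a dataset from CSV
#'
#' Reads a comma-separated file with a header row, selects the response and
#' predictor columns, coerces them to numeric, drops rows with missing
#' values (with a message reporting the count), applies the requested
#' per-column transforms in declared order, and validates that the
#' predictors are non-negative afterwards.
#'
#' @param path Path to a CSV file (comma separator, header row, `.` decimal).
#' @param response Name of the response column.
#' @param predictors Character vector of 2 or 3 predictor column names.
#' @param transforms Optional named list/vector mapping column names to one
#'   of `"none"`, `"log1p"`, `"standardize01"`, `"both"` (log1p first).
#' @return An [fpir_data] object with attribute `"transforms"` (a list of
#'   per-column records including the min/max used by `standardize01`).
#' @export
load_table <- function(path, response, predictors, transforms = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  cols <- c(response, predictors)
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols)) {
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!length(predictors) %in% c(2L, 3L)) {
    stop("2 or 3 predictor columns required", call. = FALSE)
  }
  num <- lapply(cols, function(cl) {
    v <- raw[[cl]]
    out <- suppressWarnings(as.numeric(as.character(v)))
    bad <- which(is.na(out) & !is.na(v) & trimws(as.character(v)) != "" &
                   tolower(trimws(as.character(v))) != "na")
    if (length(bad)) {
      stop("column '", cl, "' is not numeric (first offending row: ",
           bad[1], ")", call. = FALSE)
    }
    out
  })
  names(num) <- cols

  tmeta <- list()
  for (cl in cols) {
    kind <- if (!is.null(transforms) && !is.null(transforms[[cl]]))
      transforms[[cl]] else "none"
    tr <- apply_transform(num[[cl]], kind, cl)
    num[[cl]] <- tr$values
    tmeta[[cl]] <- tr$meta
  }

  x <- do.call(cbind, num[predictors])
  colnames(x) <- predictors
  data <- fpir_data(num[[response]], x)
  if (data$dropped > 0) {
    message("dropped ", data$dropped, " row(s) with missing values (",
            data$n, " retained)")
  }
  if (any(data$x < 0)) {
    neg <- predictors[apply(data$x < 0, 2, any)]
    stop("predictor(s) negative after transforms: ",
         paste(neg, collapse = ", "),
         "; apply log1p and/or standardize01", call. = FALSE)
  }
  attr(data, "transforms") <- tmeta
  attr(data, "response") <- response
  data
}
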