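#' Initial exponent candidate grid
#'
#' The stage-1 grid holds 55 candidate exponent values spanning
#' \[-52.5, 52.5\], symmetric about zero and sampled more densely near zero.
#' The positive half is the power-scaled sequence
#' `52.5 * (i/27)^gamma` for `i = 1..27` with
#' `gamma = log(52.5)/log(27/4)`, chosen so that the value 1 falls exactly
#' on the grid (at `i = 4`); the negative half is its mirror image and 0 is
#' included. Containing 1 exactly guarantees that the classical interaction
#' model (both exponents 1) is always among the candidates, so the searched
#' model can never fit worse than the regular regression.
#'
#' @return An object of class `fpir_grid` with elements `values` (ordered
#'   numeric vector of length 55), `stage` (`"initial"`) and `span`.
#' @examples
#' g <- make_initial_grid()
#' length(g$values); range(g$values)
#' @export
make_initial_grid <- function() {
  gamma <- log(52.5) / log(27 / 4)
  pos <- 52.5 * (seq_len(27) / 27)^gamma
  pos[4] <- 1       # exact by choice of gamma; pin against rounding
  pos[27] <- 52.5
  values <- c(-rev(pos), 0, pos)
  structure(list(values = values, stage = "initial", span = range(values)),
            class = "fpir_grid")
}

# step of every stage-2 grid: 10 evenly spaced values across a +/-3.5 window
tuned_step <- function() 7 / 9

#' Stage-2 tuning grid around a stage-1 winner
#'
#' Ten evenly spaced values centred on a member of the initial grid,
#' spanning `center +/- 3.5` (step 7/9). Taken over all 55 possible
#' centers this yields 550 distinct reachable values per exponent within
#' \[-56, 56\] (the window extends 3.5 beyond the extreme centers
#' at +/-52.5), i.e. 302,500 reachable exponent pairs in total.
#'
#' @param center A value of the initial grid (the stage-1 winner).
#' @param initial The initial grid, from [make_initial_grid()].
#' @return An `fpir_grid` with 10 values and stage `"tuned"`.
#' @export
make_tuning_grid <- function(center, initial = make_initial_grid()) {
  if (!any(abs(initial$values - center) < 1e-9)) {
    stop("`center` (", center, ") is not a value of the initial grid",
         call. = FALSE)
  }
  values <- seq(center - 3.5, center + 3.5, length.out = 10)
  structure(list(values = values, stage = "tuned", span = range(values)),
            class = "fpir_grid")
}

#' All exponent values reachable by the two-stage search
#'
#' Union of the stage-2 grids over every initial-grid center: the complete
#' candidate set for one exponent (550 values in \[-56, 56\]).
#'
#' @param initial The initial grid.
#' @return Sorted numeric vector of reachable exponent values.
#' @export
reachable_exponents <- function(initial = make_initial_grid()) {
  sort(unlist(lapply(initial$values,
                     function(c) make_tuning_grid(c, initial)$values)))
}

#' @export
print.fpir_grid <- function(x, ...) {
  cat("<fpir_grid> stage ", x$stage, ": ", length(x$values),
      " values in [", x$span[1], ", ", x$span[2], "]\n", sep = "")
  invisible(x)
}
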