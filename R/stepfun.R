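#' Right-continuous step function
#'
#' Container for nondecreasing (cumulative hazard) or nonincreasing (survival)
#' step estimates. Evaluation is right-continuous: the value at `t` is the
#' value at the largest knot `<= t`; before the first knot the function equals
#' `v0` (0 for cumulative hazards, 1 for survival curves). A left-limit mode
#' gives the value at the largest knot strictly `< t`, which censoring-time
#' imputation needs for the conditioning event `C > Ti`.
#'
#' @param knots Strictly increasing positive knot locations.
#' @param values Function values at the knots.
#' @param v0 Value before the first knot.
#' @param type `"cumhaz"` or `"surv"` (used for validation and printing).
#' @return An object of class `fg_stepfun`.
#' @export
fg_stepfun <- function(knots, values, v0, type = c("cumhaz", "surv")) {
  type <- match.arg(type)
  if (length(knots) != length(values)) stop_fgmi("knots and values must have equal length")
  if (is.unsorted(knots, strictly = TRUE)) stop_fgmi("knots must be strictly increasing")
  if (length(knots) && any(knots <= 0)) stop_fgmi("knots must be positive")
  if (type == "cumhaz" && is.unsorted(c(v0, values))) stop_fgmi("cumulative hazard must be nondecreasing")
  if (type == "surv" && is.unsorted(rev(c(v0, values)))) stop_fgmi("survival curve must be nonincreasing")
  structure(list(knots = as.numeric(knots), values = as.numeric(values),
                 v0 = v0, type = type),
            class = "fg_stepfun")
}

#' Evaluate a step function
#'
#' @param sf An [fg_stepfun].
#' @param t Evaluation times.
#' @param left If `TRUE`, return the left limit (value at the largest knot
#'   strictly below `t`) instead of the right-continuous value.
#' @return Numeric vector of the same length as `t`.
#' @export
step_eval <- function(sf, t, left = FALSE) {
  idx <- findInterval(t, sf$knots, left.open = left)
  c(sf$v0, sf$values)[idx + 1L]
}

#' @export
print.fg_stepfun <- function(x, ...) {
  cat(sprintf("<fg_stepfun: %s, %d knots on [%.4g, %.4g]>\n", x$type,
              length(x$knots),
              if (length(x$knots)) min(x$knots) else NA, if (length(x$knots)) max(x$knots) else NA))
  invisible(x)
}

#' @rdname fg_stepfun
#' @param x An `fg_stepfun`.
#' @param ... Unused.
#' @method tidy fg_stepfun
#' @export
tidy.fg_stepfun <- function(x, ...) {
  tibble::tibble(time = x$knots, value = x$values)
}
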