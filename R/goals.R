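#' Goal range for a physiologic or laboratory variable
#'
#' A goal range states the interval a variable should occupy.  Bounds may be
#' one-sided ("SpO2 > 90" has no upper bound) and are strict by default,
#' honoring the usual clinical phrasing: a value sitting exactly on a strict
#' bound has \emph{not} attained the goal (SpO2 = 90 is below goal, plateau
#' pressure = 30 is above goal).
#'
#' @param variable name of the variable the range applies to.
#' @param lower,upper numeric bounds; `NA` for a one-sided goal.
#' @param strict_lower,strict_upper logical; if `TRUE` the bound itself is
#'   outside the goal range.
#' @return An object of class `goal_range`.
#' @examples
#' g <- goal_range("spo2", lower = 90)
#' classify_goal(g, c(88, 90, 95))   # below below within
#' @export
goal_range <- function(variable, lower = NA_real_, upper = NA_real_,
                       strict_lower = TRUE, strict_upper = TRUE) {
  if (is.na(lower) && is.na(upper))
    stop("goal_range needs at least one bound", call. = FALSE)
  if (!is.na(lower) && !is.na(upper) && lower >= upper)
    stop("goal_range lower bound must be below upper bound", call. = FALSE)
  structure(
    list(variable = as.character(variable),
         lower = as.numeric(lower), upper = as.numeric(upper),
         strict_lower = isTRUE(strict_lower),
         strict_upper = isTRUE(strict_upper)),
    class = "goal_range")
}

#' Classify values against a goal range
#'
#' @param g a [goal_range()].
#' @param x numeric vector of observed values.
#' @return Character vector in `c("below", "within", "above")`.  One-sided
#'   goals never emit their unbounded side.
#' @export
classify_goal <- function(g, x) {
  stopifnot(inherits(g, "goal_range"))
  out <- rep("within", length(x))
  if (!is.na(g$lower)) {
    fail <- if (g$strict_lower) x <= g$lower else x < g$lower
    out[fail] <- "below"
  }
  if (!is.na(g$upper)) {
    fail <- if (g$strict_upper) x >= g$upper else x > g$upper
    out[fail] <- "above"
  }
  out[is.na(x)] <- NA_character_
  out
}

#' @export
print.goal_range <- function(x, ...) {
  lo <- if (is.na(x$lower)) "" else
    paste0(x$lower, if (x$strict_lower) " < " else " <= ")
  hi <- if (is.na(x$upper)) "" else
    paste0(if (x$strict_upper) " < " else " <= ", x$upper)
  cat("<goal_range> ", lo, x$variable, hi, "\n", sep = "")
  invisible(x)
}

#' Default mechanical-ventilation goal ranges
#'
#' Oxygen saturation > 90\%, pH between a disease-specific lower bound
#' (default 7.30) and 7.45, mean arterial pressure > 65 mmHg, and plateau
#' pressure < 30 cmH2O.
#'
#' @param ph_lb lower pH bound; disease-process specific, default 7.30.
#' @return Named list of [goal_range()] objects for `spo2`, `ph`, `map`,
#'   `pplat`.
#' @export
mv_goals <- function(ph_lb = 7.30) {
  list(
    spo2  = goal_range("spo2", lower = 90),
    ph    = goal_range("ph", lower = ph_lb, upper = 7.45),
    map   = goal_range("map", lower = 65),
    pplat = goal_range("pplat", upper = 30))
}

#' Default dialysis anemia-management target ranges
#'
#' Hemoglobin 10--12 g/dL (inclusive), iron saturation > 20\%, ferritin
#' between 200 and 500 ng/mL (exclusive).
#'
#' @return Named list of [goal_range()] objects for `hgb`, `ferritin`,
#'   `tsat`.
#' @export
hd_targets <- function() {
  list(
    hgb      = goal_range("hgb", lower = 10, upper = 12,
                          strict_lower = FALSE, strict_upper = FALSE),
    ferritin = goal_range("ferritin", lower = 200, upper = 500),
    tsat     = goal_range("tsat", lower = 20))
}
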