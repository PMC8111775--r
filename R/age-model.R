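#' Position-to-age model for the leaf developmental gradient
#'
#' In an elongating cereal leaf, a cell's distance from the base encodes the
#' time elapsed since it left the basal meristem, but the relation is strongly
#' non-linear: cells spend long at the base and are then displaced quickly as
#' the elongation zone pushes them towards the tip. An `age_model` couples a
#' monotone lookup table (position in mm from the leaf base to cell age in
#' days) with the leaf elongation rates measured in the experiment at hand, so
#' that ages read off a published reference gradient can be rescaled to the
#' observed growth speed.
#'
#' @param lookup A data frame with numeric columns `position_mm` and
#'   `age_days`, strictly increasing in `position_mm` and non-decreasing in
#'   `age_days`. Defaults to a packaged synthetic saturating curve (see
#'   [default_age_lookup()]).
#' @param elongation_rates Numeric vector of observed leaf elongation rates in
#'   mm/day, one per consecutive day of the gradient (defaults 44, 43, 42).
#' @param reference_rate The elongation rate (mm/day) under which `lookup` was
#'   established. Ages are rescaled by `reference_rate / observed rate`.
#'
#' @return An object of class `ptj_age_model`.
#' @seealso [position_to_age()]
#' @export
#' @examples
#' am <- age_model()
#' position_to_age(c(0, 7.5, 80), am)
age_model <- function(lookup = default_age_lookup(),
                      elongation_rates = c(44, 43, 42),
                      reference_rate = elongation_rates[1]) {
  lookup <- as_tibble(lookup)
  check_columns(lookup, c("position_mm", "age_days"), "lookup")
  if (nrow(lookup) < 2) {
    ptj_abort("`lookup` needs at least two knots.", "ptj_error_argument")
  }
  if (is.unsorted(lookup$position_mm, strictly = TRUE)) {
    ptj_abort("`lookup$position_mm` must be strictly increasing.",
              "ptj_error_argument")
  }
  if (is.unsorted(lookup$age_days)) {
    ptj_abort("`lookup$age_days` must be non-decreasing.",
              "ptj_error_argument")
  }
  check_number(elongation_rates, "elongation_rates", lower = 1e-9)
  check_number(reference_rate, "reference_rate", lower = 1e-9)
  structure(
    list(lookup = lookup, elongation_rates = elongation_rates,
         reference_rate = reference_rate),
    class = "ptj_age_model"
  )
}

#' Default synthetic position/age lookup
#'
#' A monotone saturating position-to-age curve standing in for a measured
#' reference gradient of a cereal first leaf elongating at ~44 mm/day. It is a
#' synthetic calibration, chosen so that cells 5--10 mm from the base are under
#' one day old, the basal 15 mm span roughly the first day, and cells at 80 mm
#' are close to three days old. Replace it with a measured table via
#' [age_model()] whenever one is available.
#'
#' @return A tibble with columns `position_mm`, `age_days`.
#' @export
default_age_lookup <- function() {
  tibble(
    position_mm = c(0, 2.5, 7.5, 12.5, 17.5, 22.5, 27.5, 32.5, 37.5,
                    50, 65, 80, 95, 110),
    age_days    = c(0, 0.30, 0.75, 1.00, 1.25, 1.50, 1.70, 1.90, 2.10,
                    2.40, 2.65, 2.90, 3.20, 3.50)
  )
}

#' Convert leaf positions to cell ages
#'
#' Monotone linear interpolation of the model's lookup, followed by a
#' multiplicative time rescaling `reference_rate / observed_rate`: a leaf
#' elongating slower than the reference takes proportionally longer to carry a
#' cell to the same position. The observed rate used for a position is that of
#' the day in which the (uncorrected) age falls; days beyond the supplied
#' rates reuse the last rate.
#'
#' @param midpoint_mm Numeric vector of positions (mm from the leaf base).
#' @param model A [age_model()] object.
#' @return Numeric vector of ages in days.
#' @export
position_to_age <- function(midpoint_mm, model = age_model()) {
  if (!inherits(model, "ptj_age_model")) {
    ptj_abort("`model` must be an `age_model()` object.", "ptj_error_argument")
  }
  check_number(midpoint_mm, "midpoint_mm")
  rng <- range(model$lookup$position_mm)
  if (any(midpoint_mm < rng[1] | midpoint_mm > rng[2])) {
    ptj_abort(sprintf(
      "position(s) outside the lookup domain [%g, %g] mm.", rng[1], rng[2]),
      class = "ptj_error_range")
  }
  raw <- stats::approx(model$lookup$position_mm, model$lookup$age_days,
                       xout = midpoint_mm, method = "linear", ties = "ordered")$y
  day <- pmin(pmax(ceiling(raw), 1), length(model$elongation_rates))
  observed <- model$elongation_rates[day]
  raw * model$reference_rate / observed
}

#' @export
print.ptj_age_model <- function(x, ...) {
  cat("<ptj_age_model>\n")
  cat(sprintf("  lookup: %d knots over [%g, %g] mm -> [%g, %g] days\n",
              nrow(x$lookup), min(x$lookup$position_mm),
              max(x$lookup$position_mm), min(x$lookup$age_days),
              max(x$lookup$age_days)))
  cat(sprintf("  elongation rates: %s mm/day (reference %g)\n",
              paste(x$elongation_rates, collapse = ", "), x$reference_rate))
  invisible(x)
}
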