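#' Per-sample summaries of cell and plastid microscopy measurements
#'
#' Pools cells across replicates within each sample and reports median,
#' quartiles and full range for cell plan area, plastid count per cell, and
#' mean individual plastid plan area, together with the per-sample means used
#' downstream by the rate calculations.
#'
#' @param cells A data frame with columns `sample_id`, `replicate`, `cell_id`,
#'   `cell_area`, `plastid_count`, `mean_plastid_area` (plan areas in um^2).
#' @param expected_samples Optional vector of sample ids that must all be
#'   present; an absent sample raises an error naming it.
#' @param min_cells Minimum cells per sample (default 5).
#' @return A tibble with one row per sample and summary columns
#'   `<var>_median`, `<var>_q1`, `<var>_q3`, `<var>_min`, `<var>_max`,
#'   `<var>_mean` for the three measured variables, plus `n_cells` and
#'   `total_plastid_area_mean` (= mean plastid count x mean plastid area).
#' @export
summarize_cells <- function(cells, expected_samples = NULL, min_cells = 5) {
  cells <- as_tibble(cells)
  check_columns(cells, c("sample_id", "cell_area", "plastid_count",
                         "mean_plastid_area"), "cells")
  if (!is.null(expected_samples)) {
    absent <- setdiff(expected_samples, unique(cells$sample_id))
    if (length(absent) > 0) {
      ptj_abort(sprintf("sample %s has no cells",
                        paste(absent, collapse = ", ")),
                class = "ptj_error_missing_sample")
    }
  }
  if (any(cells$cell_area <= 0) || any(cells$mean_plastid_area <= 0) ||
      any(cells$plastid_count < 1)) {
    ptj_abort("cell/plastid areas must be positive and counts >= 1.",
              "ptj_error_argument")
  }
  five <- function(x, prefix) {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    out <- list(q[2], q[1], q[3], min(x), max(x), mean(x))
    names(out) <- paste0(prefix, c("_median", "_q1", "_q3", "_min", "_max",
                                   "_mean"))
    out
  }
  out <- cells %>%
    group_by(.data$sample_id) %>%
    summarise(
      n_cells = dplyr::n(),
      as_tibble(c(five(.data$cell_area, "cell_area"),
                  five(.data$plastid_count, "plastid_count"),
                  five(.data$mean_plastid_area, "mean_plastid_area"))),
      .groups = "drop"
    ) %>%
    mutate(total_plastid_area_mean =
             .data$plastid_count_mean * .data$mean_plastid_area_mean) %>%
    arrange(.data$sample_id)
  low <- out$sample_id[out$n_cells < min_cells]
  if (length(low) > 0) {
    ptj_abort(sprintf("sample %s has fewer than %d cells",
                      paste(low, collapse = ", "), min_cells),
              class = "ptj_error_argument")
  }
  out
}

#' Division-corrected plastid division rate
#'
#' Rate of organelle division rounds per day across a sample transition,
#' corrected for the halving of per-cell counts caused by cell division:
#' \deqn{r_i = \log_2\!\big(N_{i+1} C_i / N_i\big) / (t_{i+1} - t_i)}
#' where `N` is the mean plastid count per cell, `C_i` the cell-division
#' correction factor of the transition, and `t` the cell age in days.
#' Negative rates are meaningful (a late, gradual reduction in plastid number
#' is observed in maturing tissue) and are never clipped.
#'
#' @param n_from,n_to Mean plastid counts per cell at the two samples (> 0).
#' @param correction Cell-division correction factor(s) `C_i >= 1`.
#' @param age_from,age_to Cell ages (days), `age_to > age_from`.
#' @return Rounds of plastid division per day (vectorised).
#' @export
#' @examples
#' division_rate(8, 32, 1, 0, 1 / 3)  # fourfold in 8 h -> 6 rounds/day
division_rate <- function(n_from, n_to, correction, age_from, age_to) {
  check_number(n_from, "n_from", lower = 1e-12)
  check_number(n_to, "n_to", lower = 1e-12)
  check_number(correction, "correction", lower = 1)
  if (any(age_to <= age_from)) {
    ptj_abort("`age_to` must exceed `age_from`.", "ptj_error_argument")
  }
  log2(n_to * correction / n_from) / (age_to - age_from)
}

#' Cumulative plastid division rounds over a sample range
#'
#' Total number of organelle division rounds between two samples, corrected
#' for all intervening cell divisions:
#' `log2(n_last * cumulative_correction / n_first)`.
#'
#' @param n_first,n_last Mean plastid counts per cell at the range endpoints.
#' @param cumulative_correction Product of per-transition correction factors
#'   over the range (see [cumulative_correction()]).
#' @return Rounds of division (log2 fold).
#' @export
#' @examples
#' cumulative_division_rounds(8, 72, 2)  # log2(18) ~ 4.17 rounds
cumulative_division_rounds <- function(n_first, n_last,
                                       cumulative_correction) {
  check_number(n_first, "n_first", lower = 1e-12)
  check_number(n_last, "n_last", lower = 1e-12)
  check_number(cumulative_correction, "cumulative_correction", lower = 1)
  log2(n_last * cumulative_correction / n_first)
}

#' Division-corrected chloroplast cellular growth rate
#'
#' Same contract as [division_rate()] with the total chloroplast plan area
#' per cell (`A = N x a`, plastid count times mean individual plastid area)
#' in place of the count: log2 fold of division-corrected total organelle
#' area per day.
#'
#' @param a_from,a_to Total plastid plan area per cell (um^2) at the two
#'   samples.
#' @inheritParams division_rate
#' @return log2 fold of corrected total area per day.
#' @export
growth_rate <- function(a_from, a_to, correction, age_from, age_to) {
  division_rate(a_from, a_to, correction, age_from, age_to)
}

#' Chloroplast index
#'
#' Fraction of the cell plan area occupied by the chloroplast compartment:
#' total chloroplast plan area (plastid count times mean individual plastid
#' plan area) divided by the cell plan area.
#'
#' @param plastid_count Mean plastid count per cell (> 0).
#' @param mean_plastid_area Mean individual plastid plan area (um^2, > 0).
#' @param cell_area Cell plan area (um^2, > 0).
#' @return The index (dimensionless; can marginally exceed 1 when organelle
#'   plan areas overlap the cell outline).
#' @export
#' @examples
#' chloroplast_index(100, 25, 5000)  # 0.5
chloroplast_index <- function(plastid_count, mean_plastid_area, cell_area) {
  check_number(plastid_count, "plastid_count", lower = 1e-12)
  check_number(mean_plastid_area, "mean_plastid_area", lower = 1e-12)
  check_number(cell_area, "cell_area", lower = 1e-12)
  plastid_count * mean_plastid_area / cell_area
}

#' Detect the two phases of chloroplast compartment build-up
#'
#' The corrected growth-rate series along the gradient is biphasic: an early
#' peak (plastid proliferation and enlargement), a trough, and a second peak
#' (photosynthetic chloroplast expansion). The transition is located at the
#' interior local minimum of the (optionally 3-point moving-average smoothed)
#' series that separates its two largest local maxima. Ties are broken
#' towards the earlier index. A series with no interior local minimum (e.g.
#' monotone) has no biphasic structure and raises an error.
#'
#' @param rates Numeric growth-rate series (length >= 5), ordered along the
#'   gradient.
#' @param smooth Apply 3-point moving-average smoothing first (default TRUE).
#' @return A list with `transition` (index into `rates`), `plastid_phase`
#'   (indices before the transition), `chloroplast_phase` (indices after).
#' @export
detect_phases <- function(rates, smooth = TRUE) {
  check_number(rates, "rates")
  n <- length(rates)
  if (n < 5) {
    ptj_abort("`rates` must have length >= 5.", "ptj_error_argument")
  }
  x <- rates
  if (isTRUE(smooth)) {
    x <- vapply(seq_len(n), function(i) {
      mean(rates[max(1, i - 1):min(n, i + 1)])
    }, numeric(1))
  }
  interior <- 2:(n - 1)
  is_min <- vapply(interior, function(i) {
    x[i] <= x[i - 1] && x[i] <= x[i + 1] && (x[i] < x[i - 1] || x[i] < x[i + 1])
  }, logical(1))
  is_max <- vapply(interior, function(i) {
    x[i] >= x[i - 1] && x[i] >= x[i + 1] && (x[i] > x[i - 1] || x[i] > x[i + 1])
  }, logical(1))
  minima <- interior[is_min]
  # Endpoints count as candidate maxima so a hump truncated at the series
  # boundary still anchors the biphasic pattern.
  maxima <- sort(unique(c(1L, n, interior[is_max])))
  if (length(minima) == 0) {
    ptj_abort("no biphasic structure: growth-rate series has no interior local minimum.",
              class = "ptj_error_no_biphasic")
  }
  ord <- order(-x[maxima], maxima)
  top2 <- sort(maxima[ord[1:2]])
  between <- minima[minima > top2[1] & minima < top2[2]]
  if (length(between) == 0) between <- minima
  transition <- between[which.min(x[between])]  # which.min: earliest on ties
  list(
    transition = transition,
    plastid_phase = seq_len(transition - 1),
    chloroplast_phase = seq(transition + 1, n)
  )
}
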