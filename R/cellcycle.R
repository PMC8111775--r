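#' Cell-division correction factor from S-phase fractions
#'
#' In a proliferating tissue each cell division halves, on average, the number
#' of organelles per cell, so per-cell organelle counts understate organelle
#' proliferation. The correction factor for a sample transition restores the
#' halving: it equals 2 when every cell divides once over the transition (full
#' cycling, as at the meristem-to-leaf-base step) and 1 when no cells divide.
#' In the absence of endoreduplication every nucleus in S phase proceeds to
#' mitosis, so the fraction of divisions completed is indexed by the S-phase
#' fraction relative to the fully cycling reference sample:
#' \deqn{C_i = 1 + \min(1, f_{S,i} / f_{S,\mathrm{ref}})}
#' clipped to `[1, 2]` (at most one division per transition).
#'
#' S-phase fractions "barely detectable above background" are treated as zero:
#' values below `floor` are zeroed before the ratio is taken.
#'
#' @param f_s S-phase nuclear fraction(s) of the upstream sample of each
#'   transition, in `[0, 1]`.
#' @param f_s_reference S-phase fraction of the fully cycling reference
#'   (meristem) sample; must be positive.
#' @param floor Detection floor below which `f_s` is treated as 0
#'   (default 0.01).
#' @return Correction factor(s) in `[1, 2]`.
#' @export
#' @examples
#' correction_factor(0.30, 0.30)  # full cycling -> 2
#' correction_factor(0.24, 0.30)  # -> 1.8
#' correction_factor(0, 0.30)     # quiescent -> 1
correction_factor <- function(f_s, f_s_reference, floor = 0.01) {
  check_number(f_s, "f_s", lower = 0)
  if (!is.numeric(f_s_reference) || length(f_s_reference) != 1 ||
      is.na(f_s_reference) || f_s_reference <= 0) {
    ptj_abort("`f_s_reference` must be a single positive number.",
              "ptj_error_argument")
  }
  check_number(floor, "floor", lower = 0)
  f_s <- ifelse(f_s < floor, 0, f_s)
  pmin(pmax(1 + pmin(1, f_s / f_s_reference), 1), 2)
}

#' Per-transition correction factors for a cell-cycle profile
#'
#' Tabulates [correction_factor()] over consecutive sample transitions of a
#' flow-cytometry cell-cycle profile. The upstream sample's S-phase fraction
#' is used for each transition; the reference is sample 1 (the meristem)
#' unless overridden.
#'
#' @param cell_cycle A data frame with columns `sample_id`, `f_s` (and
#'   optionally `f_g1`, `f_g2`, `n_nuclei`), one row per sample, ordered by
#'   `sample_id`.
#' @param reference_sample `sample_id` of the fully cycling reference
#'   (default: the first).
#' @inheritParams correction_factor
#' @return A tibble with columns `from_sample`, `to_sample`, `f_s`, `factor`.
#' @export
correction_factors <- function(cell_cycle, reference_sample = NULL,
                               floor = 0.01) {
  cell_cycle <- as_tibble(cell_cycle)
  check_columns(cell_cycle, c("sample_id", "f_s"), "cell_cycle")
  cell_cycle <- arrange(cell_cycle, .data$sample_id)
  if (nrow(cell_cycle) < 2) {
    ptj_abort("need at least two samples to form a transition.",
              "ptj_error_argument")
  }
  reference_sample <- reference_sample %||% cell_cycle$sample_id[1]
  f_ref <- cell_cycle$f_s[match(reference_sample, cell_cycle$sample_id)]
  if (is.na(f_ref)) {
    ptj_abort("`reference_sample` not found in `cell_cycle`.",
              "ptj_error_argument")
  }
  n <- nrow(cell_cycle)
  tibble(
    from_sample = cell_cycle$sample_id[-n],
    to_sample   = cell_cycle$sample_id[-1],
    f_s         = cell_cycle$f_s[-n],
    factor      = correction_factor(cell_cycle$f_s[-n], f_ref, floor = floor)
  )
}

#' Cumulative cell-division correction over a sample range
#'
#' Product of per-transition correction factors; its log2 is the number of
#' cell-division rounds undergone across the range.
#'
#' @param factors Numeric vector of per-transition factors, each `>= 1`,
#'   ordered along the gradient; or the tibble returned by
#'   [correction_factors()].
#' @param from_sample,to_sample Range of samples (inclusive endpoints); the
#'   factors used are those of transitions starting in `[from_sample,
#'   to_sample - 1]`. When `factors` is a bare vector the range indexes its
#'   elements directly.
#' @return A single number `>= 1`.
#' @export
#' @examples
#' cumulative_correction(c(2, 1.8, 1))  # 3.6
cumulative_correction <- function(factors, from_sample = NULL,
                                  to_sample = NULL) {
  if (is.data.frame(factors)) {
    check_columns(factors, c("from_sample", "factor"), "factors")
    from_sample <- from_sample %||% min(factors$from_sample)
    to_sample <- to_sample %||% (max(factors$from_sample) + 1L)
    keep <- factors$from_sample >= from_sample &
      factors$from_sample < to_sample
    factors <- factors$factor[keep]
  } else if (!is.null(from_sample) || !is.null(to_sample)) {
    from_sample <- from_sample %||% 1L
    to_sample <- to_sample %||% (length(factors) + 1L)
    if (from_sample >= to_sample) {
      ptj_abort("`from_sample` must be < `to_sample`.", "ptj_error_argument")
    }
    factors <- factors[seq(from_sample, to_sample - 1)]
  }
  if (length(factors) == 0) {
    ptj_abort("empty transition range.", "ptj_error_argument")
  }
  check_number(factors, "factors", lower = 1)
  prod(factors)
}

#' Cell doubling time from relative S-phase fraction
#'
#' If the fully cycling reference population completes a cycle in
#' `full_cycle_hours` (the fastest recorded wheat cell cycle is 12 h), a
#' population with a fraction `f_s / f_s_reference` of cells in S phase cycles
#' proportionally slower:
#' `doubling = full_cycle_hours / (f_s / f_s_reference)`, infinite when no
#' cells are in S phase.
#'
#' @inheritParams correction_factor
#' @param full_cycle_hours Duration of one full cycle at full speed (h).
#' @return Doubling time(s) in hours; `Inf` where `f_s` is 0.
#' @export
#' @examples
#' doubling_time(0.30, 0.30)  # 12 h
#' doubling_time(0.09, 0.30)  # 40 h, ~ 2 days
doubling_time <- function(f_s, f_s_reference, full_cycle_hours = 12,
                          floor = 0.01) {
  check_number(f_s, "f_s", lower = 0)
  check_number(f_s_reference, "f_s_reference", lower = 1e-12)
  if (!is.numeric(full_cycle_hours) || full_cycle_hours <= 0) {
    ptj_abort("`full_cycle_hours` must be positive.", "ptj_error_argument")
  }
  f_s <- ifelse(f_s < floor, 0, f_s)
  ifelse(f_s == 0, Inf, full_cycle_hours / (f_s / f_s_reference))
}
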