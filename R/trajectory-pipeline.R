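#' Division-corrected organelle trajectory along the leaf gradient
#'
#' End-to-end per-sample reconstruction: summarises the per-cell microscopy
#' table, joins sample ages and cell-cycle correction factors, computes
#' per-transition plastid division and total-area growth rates (corrected for
#' cell division), per-sample chloroplast index, cumulative division rounds
#' over the plastid phase, and the plastid-to-chloroplast phase boundary.
#'
#' @param cells Per-cell microscopy table (see [summarize_cells()]).
#' @param cell_cycle Per-sample cell-cycle fractions (see
#'   [correction_factors()]).
#' @param sample_frame A data frame with `sample_id` and `age_days` (e.g. the
#'   generator's sample frame, or ages from [position_to_age()]).
#' @param floor S-phase detection floor passed to [correction_factors()].
#' @param smooth Smooth the growth-rate series before phase detection.
#' @return An object of class `ptj_trajectory`: a list with `samples`
#'   (per-sample summaries plus `chloroplast_index` and `phase` labels),
#'   `transitions` (per-transition `factor`, `division_rate`, `growth_rate`),
#'   `transition_sample`, and `cumulative_rounds` (corrected division rounds
#'   from the first sample to the end of the plastid phase).
#' @export
organelle_trajectory <- function(cells, cell_cycle, sample_frame,
                                 floor = 0.01, smooth = TRUE) {
  sample_frame <- as_tibble(sample_frame)
  check_columns(sample_frame, c("sample_id", "age_days"), "sample_frame")
  samples <- summarize_cells(cells,
                             expected_samples = sample_frame$sample_id) %>%
    left_join(select(sample_frame, "sample_id", "age_days"),
              by = "sample_id") %>%
    mutate(chloroplast_index = chloroplast_index(
      .data$plastid_count_mean, .data$mean_plastid_area_mean,
      .data$cell_area_mean)) %>%
    arrange(.data$age_days, .data$sample_id)

  fac <- correction_factors(cell_cycle, floor = floor)
  n <- nrow(samples)
  trans <- tibble(
    from_sample = samples$sample_id[-n],
    to_sample = samples$sample_id[-1],
    age_from = samples$age_days[-n],
    age_to = samples$age_days[-1],
    n_from = samples$plastid_count_mean[-n],
    n_to = samples$plastid_count_mean[-1],
    a_from = samples$total_plastid_area_mean[-n],
    a_to = samples$total_plastid_area_mean[-1]
  ) %>%
    left_join(select(fac, "from_sample", "factor"), by = "from_sample") %>%
    mutate(
      factor = dplyr::coalesce(.data$factor, 1),
      division_rate = division_rate(.data$n_from, .data$n_to, .data$factor,
                                    .data$age_from, .data$age_to),
      growth_rate = growth_rate(.data$a_from, .data$a_to, .data$factor,
                                .data$age_from, .data$age_to)
    )

  phases <- detect_phases(trans$growth_rate, smooth = smooth)
  transition_sample <- trans$from_sample[phases$transition]
  trans$phase <- c("plastid", "transition", "chloroplast")[
    1 + (seq_len(nrow(trans)) >= phases$transition) +
      (seq_len(nrow(trans)) > phases$transition)]
  samples$phase <- dplyr::case_when(
    samples$sample_id < transition_sample ~ "plastid",
    samples$sample_id == transition_sample ~ "transition",
    TRUE ~ "chloroplast"
  )

  plastid_end <- phases$transition  # last plastid-phase transition index
  cum_c <- cumulative_correction(trans$factor[seq_len(plastid_end)])
  cumulative_rounds <- cumulative_division_rounds(
    trans$n_from[1], trans$n_to[plastid_end], cum_c)

  structure(
    list(samples = samples, transitions = trans,
         transition_sample = transition_sample,
         cumulative_rounds = cumulative_rounds),
    class = "ptj_trajectory"
  )
}

#' @export
print.ptj_trajectory <- function(x, ...) {
  cat("<ptj_trajectory>\n")
  cat(sprintf("  %d samples, %d transitions\n", nrow(x$samples),
              nrow(x$transitions)))
  cat(sprintf("  phase transition at sample %s\n", x$transition_sample))
  cat(sprintf("  cumulative corrected division rounds (plastid phase): %.2f\n",
              x$cumulative_rounds))
  invisible(x)
}

#' @rdname organelle_trajectory
#' @param x A `ptj_trajectory` object.
#' @param ... Unused.
#' @method tidy ptj_trajectory
#' @export
tidy.ptj_trajectory <- function(x, ...) {
  select(x$transitions, "from_sample", "to_sample", "age_from", "age_to",
         "factor", "division_rate", "growth_rate", "phase")
}

#' @rdname organelle_trajectory
#' @method glance ptj_trajectory
#' @export
glance.ptj_trajectory <- function(x, ...) {
  tibble(
    n_samples = nrow(x$samples),
    transition_sample = x$transition_sample,
    cumulative_rounds = x$cumulative_rounds,
    max_chloroplast_index = max(x$samples$chloroplast_index)
  )
}

#' @rdname organelle_trajectory
#' @param object A `ptj_trajectory` object.
#' @method autoplot ptj_trajectory
#' @export
autoplot.ptj_trajectory <- function(object, ...) {
  trans <- object$transitions
  trans$age_mid <- (trans$age_from + trans$age_to) / 2
  long <- tidyr::pivot_longer(
    select(trans, "age_mid", "division_rate", "growth_rate"),
    cols = c("division_rate", "growth_rate"),
    names_to = "series", values_to = "rate")
  band <- trans[trans$phase == "transition", , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(.data$age_mid, .data$rate,
                                     colour = .data$series)) +
    ggplot2::geom_rect(
      data = band, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$age_from, xmax = .data$age_to),
      ymin = -Inf, ymax = Inf, fill = "grey85", alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "cell age (days)",
                  y = "division-corrected rate (log2 fold / day)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
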