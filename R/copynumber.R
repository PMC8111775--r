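#' Fit a qPCR standard curve
#'
#' Ordinary least squares of quantification cycle on log10 concentration for
#' the dilution series of one amplicon: `Cq ~ intercept + slope * log10(conc)`.
#' Amplification efficiency is derived from the slope as
#' `10^(-1/slope) - 1` (1.0 at the ideal slope of -3.3219, i.e. one cycle per
#' doubling).
#'
#' @param standards A data frame with numeric columns `concentration`
#'   (pg/ul, > 0) and `cq`, one row per standard reaction (technical
#'   replicates welcome); or two numeric vectors via `concentration`/`cq`.
#' @param amplicon Optional amplicon label stored in the result.
#' @return A `ptj_standard_curve` object with elements `amplicon`, `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `n`, `fit`.
#' @export
#' @examples
#' s <- tibble::tibble(concentration = 10^(1:-3), cq = 15 + 3.3219 * (1:5))
#' fit_standard_curve(s)$efficiency  # 1
fit_standard_curve <- function(standards, amplicon = NULL) {
  standards <- as_tibble(standards)
  check_columns(standards, c("concentration", "cq"), "standards")
  if (any(standards$concentration <= 0)) {
    ptj_abort("standard concentrations must be positive.",
              "ptj_error_argument")
  }
  n_conc <- length(unique(standards$concentration))
  if (n_conc < 3) {
    ptj_abort("need >= 3 distinct standard concentrations to fit a curve.",
              class = "ptj_error_fit")
  }
  fit <- lm(cq ~ log10(concentration), data = standards)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    ptj_abort("standard curve slope must be negative (Cq falls with concentration).",
              class = "ptj_error_fit")
  }
  structure(
    list(
      amplicon = amplicon,
      slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      # computed directly: summary.lm warns on (legitimate) perfect fits
      r_squared = 1 - sum(stats::residuals(fit)^2) /
        sum((standards$cq - mean(standards$cq))^2),
      efficiency = 10^(-1 / slope) - 1,
      n = nrow(standards),
      fit = fit
    ),
    class = "ptj_standard_curve"
  )
}

#' @export
print.ptj_standard_curve <- function(x, ...) {
  cat(sprintf(
    "<ptj_standard_curve%s> slope %.3f, intercept %.2f, E = %.1f%%, r2 = %.4f (n = %d)\n",
    if (is.null(x$amplicon)) "" else paste0(" ", x$amplicon),
    x$slope, x$intercept, 100 * x$efficiency, x$r_squared, x$n))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x,object A `ptj_standard_curve` object.
#' @param ... Unused.
#' @method tidy ptj_standard_curve
#' @export
tidy.ptj_standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname fit_standard_curve
#' @method glance ptj_standard_curve
#' @export
glance.ptj_standard_curve <- function(x, ...) {
  tibble(amplicon = x$amplicon %||% NA_character_, slope = x$slope,
         intercept = x$intercept, efficiency = x$efficiency,
         r_squared = x$r_squared, n = x$n)
}

#' @rdname fit_standard_curve
#' @method autoplot ptj_standard_curve
#' @export
autoplot.ptj_standard_curve <- function(object, ...) {
  df <- object$fit$model
  names(df) <- c("cq", "log10_conc")
  ggplot2::ggplot(df, ggplot2::aes(.data$log10_conc, .data$cq)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept, colour = "steelblue") +
    ggplot2::labs(x = "log10 concentration (pg/ul)", y = "Cq",
                  title = object$amplicon) +
    ggplot2::theme_minimal()
}

#' Absolute quantity from a standard curve
#'
#' Interpolates a Cq on the fitted curve and multiplies by the dilution
#' factor of the unknown to express the result per unit of undiluted extract:
#' `10^((cq - intercept) / slope) * dilution_factor`.
#'
#' @param cq Quantification cycle(s) of the unknown.
#' @param curve A [fit_standard_curve()] object.
#' @param dilution_factor Fold dilution applied to the unknown before the
#'   reaction (e.g. 10 for nuclear, 100 for plastid targets); default 1.
#' @return Concentration(s) in the standards' units (pg/ul of undiluted
#'   extract).
#' @export
absolute_quantity <- function(cq, curve, dilution_factor = 1) {
  if (!inherits(curve, "ptj_standard_curve")) {
    ptj_abort("`curve` must be a `ptj_standard_curve`.", "ptj_error_argument")
  }
  check_number(cq, "cq")
  check_number(dilution_factor, "dilution_factor", lower = 1)
  10^((cq - curve$intercept) / curve$slope) * dilution_factor
}

#' Plastid genome copies per haploid nuclear genome
#'
#' Ratio of the mean plastid amplicon quantity to the mean nuclear
#' single-copy amplicon quantity:
#' \deqn{\frac{(rbcL + ndhD + rps7/2)/3}{(TaKO1 + TaKS)/2}}
#' The `rps7` amplicon lies in the inverted repeat of the plastid genome and
#' is present twice per genome copy, hence the halving. Quantities must be in
#' copy-equivalent units; `copies_per_pg` supplies per-amplicon mass-to-copy
#' conversion weights (equal by default, which cancels in the ratio when all
#' amplicons share a conversion constant).
#'
#' @param rbcl,ndhd,rps7 Plastid amplicon quantities (>= 0); `rbcl` and
#'   `ndhd` are single-copy regions, `rps7` the inverted repeat.
#' @param tako1,taks Nuclear single-copy amplicon quantities (> 0).
#' @param copies_per_pg Optional named numeric vector of conversion weights
#'   for `rbcL`, `ndhD`, `rps7`, `TaKO1`, `TaKS`.
#' @return Plastid genome copies per haploid nuclear genome (vectorised).
#' @export
#' @examples
#' cpdna_per_genome(300, 270, 630, 2.0, 2.2)  # ~ 140.5
cpdna_per_genome <- function(rbcl, ndhd, rps7, tako1, taks,
                             copies_per_pg = NULL) {
  check_number(rbcl, "rbcl", lower = 0)
  check_number(ndhd, "ndhd", lower = 0)
  check_number(rps7, "rps7", lower = 0)
  check_number(tako1, "tako1", lower = 1e-300)
  check_number(taks, "taks", lower = 1e-300)
  w <- c(rbcL = 1, ndhD = 1, rps7 = 1, TaKO1 = 1, TaKS = 1)
  if (!is.null(copies_per_pg)) {
    if (is.null(names(copies_per_pg)) ||
        !all(names(copies_per_pg) %in% names(w))) {
      ptj_abort("`copies_per_pg` must be named with amplicon names.",
                "ptj_error_argument")
    }
    w[names(copies_per_pg)] <- copies_per_pg
  }
  plastid <- (rbcl * w["rbcL"] + ndhd * w["ndhD"] + rps7 * w["rps7"] / 2) / 3
  nuclear <- (tako1 * w["TaKO1"] + taks * w["TaKS"]) / 2
  unname(plastid / nuclear)
}

#' Plastid ribosome build-up as the 16S/18S rRNA ratio
#'
#' Ratio of plastid 16S rRNA to cytosolic 18S rRNA absolute quantities (or
#' electropherogram peak areas), indexing the share of cellular translation
#' capacity invested in the organelle.
#'
#' @param q16s Quantity of 16S rRNA (>= 0).
#' @param q18s Quantity of 18S rRNA (> 0).
#' @return The ratio (vectorised).
#' @export
rrna_ratio <- function(q16s, q18s) {
  check_number(q16s, "q16s", lower = 0)
  if (any(q18s <= 0)) {
    ptj_abort("`q18s` must be positive.", "ptj_error_argument")
  }
  q16s / q18s
}

#' Aggregate technical then biological replicates
#'
#' Technical replicates are averaged within each biological replicate first;
#' the mean and the standard error of the mean are then taken across
#' biological replicates.
#'
#' @param values Numeric vector of measurements.
#' @param biological Vector identifying the biological replicate of each
#'   value (technical replicates share an id).
#' @return A tibble with `mean`, `sem` (NA with a single biological
#'   replicate), `n_biological`.
#' @export
#' @examples
#' aggregate_replicates(c(1, 3, 2, 2), c("a", "a", "b", "b"))
aggregate_replicates <- function(values, biological = seq_along(values)) {
  check_number(values, "values")
  if (length(biological) != length(values)) {
    ptj_abort("`biological` must match `values` in length.",
              "ptj_error_argument")
  }
  bio <- tapply(values, biological, mean)
  n <- length(bio)
  tibble(
    mean = mean(bio),
    sem = if (n > 1) sd(bio) / sqrt(n) else NA_real_,
    n_biological = n
  )
}
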