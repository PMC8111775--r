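#' Configuration for the synthetic leaf-gradient experiment
#'
#' Collects every knob of the synthetic-data generator. Defaults reproduce
#' the design of the study the package models: 15 ordered samples along the
#' first-leaf gradient (sample 1 the shoot apex, sample 15 the mature
#' blade), 3 biological replicates, 48 measured cells per sample, ~30% of
#' meristem nuclei in S phase, 4.5 total rounds of organelle division, qPCR
#' standards spanning 25 to 0.0025 pg/ul, and 12 staggered-peak expression
#' modules with negative-binomial replicate noise.
#'
#' @param n_samples Number of gradient samples. The packaged trajectory
#'   templates define the 15-sample design; only 15 is supported.
#' @param n_replicates Biological replicates per sample (default 3).
#' @param n_genes Number of simulated (non-regulator) genes (default 600).
#' @param n_modules Number of planted co-expression modules (default 12).
#' @param module_peak_samples Sample index at which each module peaks;
#'   length `n_modules`, values in `1..n_samples`.
#' @param frac_dynamic Fraction of genes planted as dynamic (default 0.6);
#'   the rest are flat.
#' @param nb_dispersion Negative-binomial size parameter of replicate count
#'   noise (default 20, i.e. ~13% CV on replicate-averaged sample means);
#'   `Inf` gives Poisson noise.
#' @param library_size,library_cv Mean sequencing depth per library
#'   (default 2e7 reads) and its lognormal CV (default 0.2).
#' @param n_cells_per_sample Measured cells per sample (default 48).
#' @param cell_area_cv,plastid_count_cv,plastid_area_cv Cell-to-cell
#'   lognormal CVs of the three microscopy measurements (defaults 0.30,
#'   0.25, 0.25).
#' @param s_phase_start S-phase nuclear fraction of the meristem sample
#'   (default 0.30).
#' @param organelle_rounds_total Total planted rounds of organelle division
#'   over the plastid phase (default 4.5).
#' @param biphasic_params Integer triple (plastid-phase peak transition,
#'   trough transition, chloroplast-phase peak transition) anchoring the
#'   planted growth-rate series (default `c(3, 8, 11)`).
#' @param qpcr_efficiencies Named per-amplicon amplification efficiencies
#'   (default 0.95 for rbcL, ndhD, rps7, TaKO1, TaKS).
#' @param standard_range `(max, min)` standard concentrations in pg/ul
#'   (default `c(25, 0.0025)`), spanned by 5 ten-fold dilutions.
#' @param cq_sd,cq_sd_standard Cq noise standard deviations for unknowns
#'   (default 0.15) and purified standards (default 0.05).
#' @param planted_edges Data frame `regulator`, `target_rank`, `effect`
#'   describing planted regulator-to-target dependencies (default: 4
#'   regulators x 3 targets, effect 1.5); targets are assigned to dynamic
#'   plastid-localised genes at generation time.
#' @param seed Integer master seed; all per-table substreams derive from it
#'   by fixed offsets, so adding a table never perturbs the others.
#' @return A validated `ptj_sim_config` list.
#' @export
sim_config <- function(n_samples = 15,
                       n_replicates = 3,
                       n_genes = 600,
                       n_modules = 12,
                       module_peak_samples = NULL,
                       frac_dynamic = 0.6,
                       nb_dispersion = 20,
                       library_size = 2e7,
                       library_cv = 0.2,
                       n_cells_per_sample = 48,
                       cell_area_cv = 0.30,
                       plastid_count_cv = 0.25,
                       plastid_area_cv = 0.25,
                       s_phase_start = 0.30,
                       organelle_rounds_total = 4.5,
                       biphasic_params = c(3, 8, 11),
                       qpcr_efficiencies = c(rbcL = 0.95, ndhD = 0.95,
                                             rps7 = 0.95, TaKO1 = 0.95,
                                             TaKS = 0.95),
                       standard_range = c(25, 0.0025),
                       cq_sd = 0.15,
                       cq_sd_standard = 0.05,
                       planted_edges = NULL,
                       seed = 1) {
  bad <- function(field, why) {
    ptj_abort(sprintf("invalid configuration: `%s` %s.", field, why),
              class = "ptj_error_config")
  }
  if (!identical(as.integer(n_samples), 15L)) {
    bad("n_samples", "must be 15 (the packaged gradient design)")
  }
  if (n_replicates < 1) bad("n_replicates", "must be >= 1")
  if (n_genes < n_modules) bad("n_genes", "must be >= n_modules")
  if (n_modules < 1) bad("n_modules", "must be >= 1")
  module_peak_samples <- module_peak_samples %||%
    default_module_peaks(n_modules, n_samples)
  if (length(module_peak_samples) != n_modules) {
    bad("module_peak_samples", "must have length n_modules")
  }
  if (any(module_peak_samples < 1 | module_peak_samples > n_samples)) {
    bad("module_peak_samples", "must lie within [1, n_samples]")
  }
  if (frac_dynamic <= 0 || frac_dynamic > 1) {
    bad("frac_dynamic", "must be in (0, 1]")
  }
  if (!(nb_dispersion > 0)) bad("nb_dispersion", "must be > 0")
  if (library_size <= 0) bad("library_size", "must be > 0")
  if (n_cells_per_sample < 5) bad("n_cells_per_sample", "must be >= 5")
  if (s_phase_start < 0 || s_phase_start > 1) {
    bad("s_phase_start", "must be in [0, 1]")
  }
  if (organelle_rounds_total <= 0) {
    bad("organelle_rounds_total", "must be > 0")
  }
  if (length(biphasic_params) != 3 || is.unsorted(biphasic_params,
                                                  strictly = TRUE)) {
    bad("biphasic_params", "must be an increasing (peak, trough, peak) triple")
  }
  if (biphasic_params[1] < 2 || biphasic_params[3] > n_samples - 1 ||
      biphasic_params[2] - biphasic_params[1] < 2) {
    bad("biphasic_params", "anchors must fit inside the transition series")
  }
  need_amp <- c("rbcL", "ndhD", "rps7", "TaKO1", "TaKS")
  if (!all(need_amp %in% names(qpcr_efficiencies)) ||
      any(qpcr_efficiencies <= 0 | qpcr_efficiencies > 1.1)) {
    bad("qpcr_efficiencies", "must name all five amplicons with values in (0, 1.1]")
  }
  if (length(standard_range) != 2 ||
      !(standard_range[1] > standard_range[2]) || standard_range[2] <= 0) {
    bad("standard_range", "must satisfy max > min > 0")
  }
  if (cq_sd < 0 || cq_sd_standard < 0) bad("cq_sd", "must be >= 0")
  planted_edges <- planted_edges %||% default_planted_edges()
  planted_edges <- as_tibble(planted_edges)
  check_columns(planted_edges, c("regulator", "effect"), "planted_edges")
  if (any(planted_edges$effect <= 0)) {
    bad("planted_edges", "effect sizes must be > 0")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    bad("seed", "must be a single integer")
  }
  structure(
    list(
      n_samples = as.integer(n_samples),
      n_replicates = as.integer(n_replicates),
      n_genes = as.integer(n_genes),
      n_modules = as.integer(n_modules),
      module_peak_samples = as.integer(module_peak_samples),
      frac_dynamic = frac_dynamic,
      nb_dispersion = nb_dispersion,
      library_size = library_size,
      library_cv = library_cv,
      n_cells_per_sample = as.integer(n_cells_per_sample),
      cell_area_cv = cell_area_cv,
      plastid_count_cv = plastid_count_cv,
      plastid_area_cv = plastid_area_cv,
      s_phase_start = s_phase_start,
      organelle_rounds_total = organelle_rounds_total,
      biphasic_params = as.integer(biphasic_params),
      qpcr_efficiencies = qpcr_efficiencies[need_amp],
      standard_range = as.numeric(standard_range),
      cq_sd = cq_sd,
      cq_sd_standard = cq_sd_standard,
      planted_edges = planted_edges,
      seed = as.integer(seed)
    ),
    class = "ptj_sim_config"
  )
}

# Peaks spread over the gradient, denser early where development is fastest.
default_module_peaks <- function(n_modules, n_samples) {
  if (n_modules == 12 && n_samples == 15) {
    return(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 11, 13, 15))
  }
  unique_peaks <- round(seq(1, n_samples, length.out = n_modules))
  pmin(pmax(unique_peaks, 1), n_samples)
}

# Candidate regulator panel mirroring the field's known chloroplast
# regulators; sign annotation marks expected direction of action.
default_regulator_panel <- function() {
  tibble(
    regulator = c("CIA2", "NCP", "RCB", "HEMERA", "GLK1", "GNC", "HY5",
                  "PIF3"),
    peak_sample = c(2L, 3L, 6L, 7L, 8L, 9L, 10L, 12L),
    sign = c(rep("positive", 7), "negative")
  )
}

default_planted_edges <- function() {
  tidyr::expand_grid(
    regulator = c("RCB", "GLK1", "HEMERA", "CIA2"),
    target_rank = 1:3
  ) %>%
    mutate(effect = 1.5)
}

#' @export
print.ptj_sim_config <- function(x, ...) {
  cat("<ptj_sim_config>\n")
  cat(sprintf("  %d samples x %d replicates; %d genes in %d modules (%.0f%% dynamic)\n",
              x$n_samples, x$n_replicates, x$n_genes, x$n_modules,
              100 * x$frac_dynamic))
  cat(sprintf("  %d cells/sample; S-phase start %.2f; %.1f organelle rounds; anchors (%s)\n",
              x$n_cells_per_sample, x$s_phase_start,
              x$organelle_rounds_total,
              paste(x$biphasic_params, collapse = ", ")))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
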