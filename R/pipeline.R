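#' Run the full analysis pipeline on an experiment bundle
#'
#' Executes the stages in dependency order on a simulated (or equivalently
#' shaped real) experiment: organelle trajectory with phase detection,
#' plastid genome copy number, 16S/18S rRNA build-up, the expression map
#' (expressed/dynamic filters, PCA, co-expression modules, enrichment), and
#' the regulator ranking restricted to dynamic genes for chloroplast-
#' targeted proteins. Stages can be toggled; the network stage requires the
#' expression stage.
#'
#' @param data A `ptj_sim` object, a bundle list from
#'   [read_fixture_bundle()], or any list with the same named tables.
#' @param stages Character vector among `"trajectory"`, `"copynumber"`,
#'   `"rrna"`, `"expression"`, `"network"` (default: all).
#' @param seed Seed for the network stage's tree ensembles.
#' @param n_trees Trees per ensemble in the network stage.
#' @param n_modules,soft_power Module-detection parameters.
#' @param out_dir Optional directory; when given, result tables are written
#'   as TSV plus a `report.json` summarising phase boundary, cumulative
#'   division rounds and module peaks.
#' @return A `ptj_report` list with the per-stage results and a `summary`
#'   list (`phase_boundary_sample`, `cumulative_rounds`, `n_dyg`,
#'   `module_peaks`, `seed`, `config_hash`).
#' @export
run_pipeline <- function(data,
                         stages = c("trajectory", "copynumber", "rrna",
                                    "expression", "network"),
                         seed = 1, n_trees = 500, n_modules = 12,
                         soft_power = 14, out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  need <- function(tb) {
    if (is.null(data[[tb]])) {
      ptj_abort(sprintf("input table '%s' is missing from `data`.", tb),
                class = "ptj_error_missing_stage")
    }
    as_tibble(data[[tb]])
  }
  if ("network" %in% stages && !("expression" %in% stages)) {
    ptj_abort("the network stage depends on the expression stage; enable both.",
              class = "ptj_error_missing_stage")
  }
  res <- list()
  summary <- list(seed = seed)

  if ("trajectory" %in% stages) {
    res$trajectory <- organelle_trajectory(
      need("cells"), need("cell_cycle"), need("sample_frame"))
    summary$phase_boundary_sample <- res$trajectory$transition_sample
    summary$cumulative_rounds <- res$trajectory$cumulative_rounds
  }
  if ("copynumber" %in% stages) {
    res$copynumber <- quantify_cpdna(need("qpcr"))
    summary$cpdna_range <- range(res$copynumber$samples$cpdna_mean)
  }
  if ("rrna" %in% stages) {
    res$rrna <- quantify_rrna(need("rrna"))
    summary$rrna_max <- max(res$rrna$rrna_ratio_mean)
  }
  if ("expression" %in% stages) {
    expr <- need("expression")
    dyg_tbl <- dyg_filter(expr)
    dyg <- attr(dyg_tbl, "dyg")
    z <- zscore_profiles(rpm_sample_means(expr)[dyg, , drop = FALSE])
    modules <- cluster_modules(z, soft_power = soft_power,
                               n_modules = n_modules)
    pca <- pca_map(expr, genes = expressed_genes(expr))
    enrichment <- if (!is.null(data$annotation)) {
      enrich_modules(modules, as_tibble(data$annotation))
    }
    res$expression <- list(dyg = dyg_tbl, modules = modules, pca = pca,
                           enrichment = enrichment)
    summary$n_dyg <- length(dyg)
    summary$module_peaks <- modules$module_peaks$peak_sample
    summary$variance_first3 <- sum(pca$variance_pct[1:3])
  }
  if ("network" %in% stages) {
    annotation <- need("annotation")
    regulators <- annotation$gene_id[annotation$class == "regulator"]
    if (length(regulators) < 2 && !is.null(data$ground_truth)) {
      regulators <- data$ground_truth$regulators$gene_id
    }
    dyg <- attr(res$expression$dyg, "dyg")
    targets <- assemble_targets(dyg, annotation, regulators)
    obs <- network_observations(need("expression"),
                                genes = c(targets, regulators))
    res$network <- rank_regulators(obs, targets, regulators,
                                   n_trees = n_trees, seed = seed)
    summary$n_targets <- length(targets)
  }
  summary$config_hash <- rlang::hash(data[["config"]] %||% stages)
  report <- structure(list(results = res, summary = summary,
                           stages = stages), class = "ptj_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.ptj_report <- function(x, ...) {
  cat("<ptj_report> stages:", paste(x$stages, collapse = ", "), "\n")
  s <- x$summary
  if (!is.null(s$phase_boundary_sample)) {
    cat(sprintf("  phase boundary at sample %s; %.2f cumulative division rounds\n",
                s$phase_boundary_sample, s$cumulative_rounds))
  }
  if (!is.null(s$n_dyg)) {
    cat(sprintf("  %d dynamic genes; module peaks: %s\n", s$n_dyg,
                paste(s$module_peaks, collapse = " ")))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) {
    ptj_abort(sprintf("cannot create '%s'.", out_dir), "ptj_error_io")
  }
  res <- report$results
  if (!is.null(res$trajectory)) {
    readr::write_tsv(tidy(res$trajectory),
                     file.path(out_dir, "trajectory.tsv"), progress = FALSE)
  }
  if (!is.null(res$copynumber)) {
    readr::write_tsv(res$copynumber$samples,
                     file.path(out_dir, "cpdna.tsv"), progress = FALSE)
  }
  if (!is.null(res$rrna)) {
    readr::write_tsv(res$rrna, file.path(out_dir, "rrna.tsv"),
                     progress = FALSE)
  }
  if (!is.null(res$expression)) {
    readr::write_tsv(res$expression$dyg, file.path(out_dir, "dyg.tsv"),
                     progress = FALSE)
    readr::write_tsv(res$expression$modules$assignment,
                     file.path(out_dir, "modules.tsv"), progress = FALSE)
  }
  if (!is.null(res$network)) {
    readr::write_tsv(tidy(res$network), file.path(out_dir, "ranking.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(report$summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
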