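#' Plastid genome copy number per sample from a raw qPCR table
#'
#' Full absolute-quantitation pipeline: per-amplicon standard curves are
#' fitted from the dilution-series rows; technical-replicate Cq values of the
#' unknowns are averaged (Cq first, then interpolation); quantities are read
#' off the curves and rescaled by each reaction's dilution factor; the
#' plastid-per-haploid-genome ratio is formed within each biological
#' replicate; and biological replicates are aggregated to a per-sample mean
#' with its standard error.
#'
#' @param qpcr A data frame with columns `amplicon` (`rbcL`, `ndhD`, `rps7`,
#'   `TaKO1`, `TaKS`), `role` (`"standard"` or `"unknown"`), `concentration`
#'   (standards only, pg/ul), `cq`, `sample_id` and `biological` (unknowns),
#'   `technical`, `dilution_factor`.
#' @inheritParams cpdna_per_genome
#' @return A list of class `ptj_cpdna` with `curves` (one
#'   [fit_standard_curve()] per amplicon), `replicates` (per biological
#'   replicate ratios) and `samples` (tibble `sample_id`, `cpdna_mean`,
#'   `cpdna_sem`, `n_biological`).
#' @export
quantify_cpdna <- function(qpcr, copies_per_pg = NULL) {
  qpcr <- as_tibble(qpcr)
  check_columns(qpcr, c("amplicon", "role", "cq"), "qpcr")
  need <- c("rbcL", "ndhD", "rps7", "TaKO1", "TaKS")
  have <- intersect(need, unique(qpcr$amplicon))
  if (length(setdiff(need, have)) > 0) {
    ptj_abort(sprintf("qpcr table lacks amplicon(s): %s.",
                      paste(setdiff(need, have), collapse = ", ")),
              "ptj_error_argument")
  }
  curves <- lapply(setNames(need, need), function(a) {
    fit_standard_curve(
      qpcr[qpcr$amplicon == a & qpcr$role == "standard", ], amplicon = a)
  })
  unknowns <- qpcr %>%
    filter(.data$role == "unknown", .data$amplicon %in% need) %>%
    group_by(.data$amplicon, .data$sample_id, .data$biological) %>%
    summarise(cq = mean(.data$cq),
              dilution_factor = .data$dilution_factor[1], .groups = "drop")
  unknowns$quantity <- vapply(seq_len(nrow(unknowns)), function(i) {
    absolute_quantity(unknowns$cq[i], curves[[unknowns$amplicon[i]]],
                      unknowns$dilution_factor[i])
  }, numeric(1))
  wide <- tidyr::pivot_wider(
    select(unknowns, "sample_id", "biological", "amplicon", "quantity"),
    names_from = "amplicon", values_from = "quantity")
  check_columns(wide, need, "unknown quantities")
  wide$cpdna <- cpdna_per_genome(wide$rbcL, wide$ndhD, wide$rps7,
                                 wide$TaKO1, wide$TaKS,
                                 copies_per_pg = copies_per_pg)
  samples <- wide %>%
    group_by(.data$sample_id) %>%
    summarise(as_tibble(setNames(
      aggregate_replicates(.data$cpdna, .data$biological),
      c("cpdna_mean", "cpdna_sem", "n_biological"))), .groups = "drop") %>%
    arrange(.data$sample_id)
  structure(list(curves = curves, replicates = wide, samples = samples),
            class = "ptj_cpdna")
}

#' @export
print.ptj_cpdna <- function(x, ...) {
  cat("<ptj_cpdna>\n")
  effs <- vapply(x$curves, function(cv) cv$efficiency, numeric(1))
  cat(sprintf("  curves: %s\n",
              paste(sprintf("%s E=%.2f", names(effs), effs), collapse = ", ")))
  cat(sprintf("  %d samples, cpDNA/genome %.1f - %.1f\n",
              nrow(x$samples), min(x$samples$cpdna_mean),
              max(x$samples$cpdna_mean)))
  invisible(x)
}

#' @rdname quantify_cpdna
#' @param x A `ptj_cpdna` object.
#' @param ... Unused.
#' @method tidy ptj_cpdna
#' @export
tidy.ptj_cpdna <- function(x, ...) x$samples

#' Per-sample 16S/18S rRNA ratio from replicate quantities
#'
#' Averages technical replicates within each biological replicate, forms the
#' plastid (16S) to cytosolic (18S) ratio per biological replicate, and
#' aggregates to a per-sample mean and standard error.
#'
#' @param rrna A data frame with columns `sample_id`, `biological`,
#'   `technical`, `target` (`"16S"`/`"18S"`), `quantity`.
#' @return A tibble `sample_id`, `rrna_ratio_mean`, `rrna_ratio_sem`,
#'   `n_biological`.
#' @export
quantify_rrna <- function(rrna) {
  rrna <- as_tibble(rrna)
  check_columns(rrna, c("sample_id", "biological", "target", "quantity"),
                "rrna")
  wide <- rrna %>%
    group_by(.data$sample_id, .data$biological, .data$target) %>%
    summarise(quantity = mean(.data$quantity), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "target", values_from = "quantity")
  check_columns(wide, c("16S", "18S"), "rrna quantities")
  wide$ratio <- rrna_ratio(wide[["16S"]], wide[["18S"]])
  wide %>%
    group_by(.data$sample_id) %>%
    summarise(as_tibble(setNames(
      aggregate_replicates(.data$ratio, .data$biological),
      c("rrna_ratio_mean", "rrna_ratio_sem", "n_biological"))),
      .groups = "drop") %>%
    arrange(.data$sample_id)
}
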