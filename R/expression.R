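#' Reads-per-million normalisation
#'
#' Library-size normalisation of a long count table: each count is divided by
#' the total counts of its library (one library per sample x replicate) and
#' scaled to one million.
#'
#' @param counts A long data frame with columns `gene_id`, `sample_id`,
#'   `replicate`, `count` (counts >= 0).
#' @return The input tibble with an added `rpm` column.
#' @export
rpm_normalize <- function(counts) {
  counts <- as_tibble(counts)
  check_columns(counts, c("gene_id", "sample_id", "replicate", "count"),
                "counts")
  if (any(counts$count < 0)) {
    ptj_abort("counts must be non-negative.", "ptj_error_argument")
  }
  out <- counts %>%
    group_by(.data$sample_id, .data$replicate) %>%
    mutate(.lib = sum(.data$count)) %>%
    ungroup()
  if (any(out$.lib <= 0)) {
    bad <- distinct(filter(out, .data$.lib <= 0),
                    .data$sample_id, .data$replicate)
    ptj_abort(sprintf(
      "zero-count library: sample %s replicate %s.",
      bad$sample_id[1], bad$replicate[1]), class = "ptj_error_library")
  }
  out %>%
    mutate(rpm = .data$count / .data$.lib * 1e6) %>%
    select(-".lib")
}

#' Replicate-averaged RPM profiles as a genes-by-samples matrix
#'
#' @param expr A long data frame with `gene_id`, `sample_id`, `replicate`,
#'   `rpm`.
#' @return A numeric matrix, genes in rows (named), samples in ordered
#'   columns.
#' @export
rpm_sample_means <- function(expr) {
  expr <- as_tibble(expr)
  check_columns(expr, c("gene_id", "sample_id", "rpm"), "expr")
  means <- expr %>%
    group_by(.data$gene_id, .data$sample_id) %>%
    summarise(rpm = mean(.data$rpm), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "rpm")
  m <- as.matrix(means[, -1])
  rownames(m) <- means$gene_id
  m[, order(as.numeric(colnames(m))), drop = FALSE]
}

#' Expressed-gene filter
#'
#' A gene is expressed when, for at least one sampling time, all biological
#' replicates reach 1 RPM. The boundary is inclusive.
#'
#' @inheritParams rpm_sample_means
#' @param threshold RPM threshold (default 1).
#' @return Character vector of expressed gene ids.
#' @export
expressed_genes <- function(expr, threshold = 1) {
  expr <- as_tibble(expr)
  check_columns(expr, c("gene_id", "sample_id", "replicate", "rpm"), "expr")
  expr %>%
    group_by(.data$gene_id, .data$sample_id) %>%
    summarise(all_above = all(.data$rpm >= threshold), .groups = "drop") %>%
    group_by(.data$gene_id) %>%
    summarise(expressed = any(.data$all_above), .groups = "drop") %>%
    filter(.data$expressed) %>%
    pull("gene_id")
}

#' Dynamically expressed gene (DYG) filter
#'
#' Works on the replicate-averaged RPM profile of each gene over the sample
#' series. A gene is dynamic when all three hold: maximum RPM >= `min_max`
#' (default 5), fold change (max/min) >= `min_fold` (default 2), and
#' coefficient of variation (sample standard deviation / mean over the sample
#' means) >= `min_cv` (default 0.2). A minimum of exactly 0 makes the fold
#' change infinite, which passes the fold criterion: a gene switching fully
#' off/on is maximally dynamic.
#'
#' @inheritParams rpm_sample_means
#' @param min_max,min_fold,min_cv The three thresholds.
#' @return A tibble with columns `gene_id`, `max_rpm`, `min_rpm`,
#'   `fold_change`, `cv`, `dynamic`; filter on `dynamic` or take
#'   `attr(, "dyg")` for the id vector.
#' @export
dyg_filter <- function(expr, min_max = 5, min_fold = 2, min_cv = 0.2) {
  m <- rpm_sample_means(expr)
  stats_tbl <- tibble(
    gene_id = rownames(m),
    max_rpm = apply(m, 1, max),
    min_rpm = apply(m, 1, min),
    mean_rpm = rowMeans(m),
    cv = apply(m, 1, sd) / rowMeans(m)
  ) %>%
    mutate(
      fold_change = ifelse(.data$min_rpm == 0, Inf,
                           .data$max_rpm / .data$min_rpm),
      cv = ifelse(.data$mean_rpm == 0, 0, .data$cv),
      dynamic = .data$max_rpm >= min_max &
        .data$fold_change >= min_fold & .data$cv >= min_cv
    ) %>%
    select("gene_id", "max_rpm", "min_rpm", "fold_change", "cv", "dynamic")
  attr(stats_tbl, "dyg") <- stats_tbl$gene_id[stats_tbl$dynamic]
  stats_tbl
}

#' Z-score expression profiles
#'
#' Standardises each gene's profile to mean 0 and standard deviation 1
#' (sample, n-1, convention) across the sample series.
#'
#' @param profiles A numeric matrix (genes x samples) or a long data frame
#'   with `gene_id`, `sample_id`, `rpm` (replicate-averaged via
#'   [rpm_sample_means()]).
#' @return A numeric matrix of Z-profiles with the input's dimnames.
#' @export
zscore_profiles <- function(profiles) {
  m <- if (is.matrix(profiles)) profiles else rpm_sample_means(profiles)
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    ptj_abort(sprintf("constant profile for gene(s): %s.",
                      paste(head(rownames(m)[sds == 0], 3), collapse = ", ")),
              class = "ptj_error_constant")
  }
  (m - rowMeans(m)) / sds
}

#' Sample index of peak expression
#'
#' Argmax of each profile; the earliest sample wins ties.
#'
#' @param profiles A matrix (genes x samples) or a single numeric profile.
#' @return Integer vector of peak positions (1-based column index), named by
#'   gene where available.
#' @export
peak_sample <- function(profiles) {
  if (!is.matrix(profiles)) profiles <- matrix(profiles, nrow = 1)
  apply(profiles, 1, which.max)
}

#' PCA map of replicate expression profiles
#'
#' Principal components of the gene-standardised expression matrix with the
#' sample x replicate libraries as observations, plus the per-component gene
#' lists used for load-factor enrichment: the top and bottom 5% (ceiling) of
#' genes sorted by loading on each component.
#'
#' @inheritParams rpm_sample_means
#' @param genes Optional gene ids to restrict to (e.g. the expressed set).
#' @param n_components Number of components to report (default 3).
#' @param load_fraction Fraction of genes in each load-factor tail
#'   (default 0.05).
#' @param standardize Standardise each gene across observations first
#'   (default TRUE); otherwise profiles are only centred.
#' @return A `ptj_pca` object with `scores` (one row per library, with
#'   `sample_id`/`replicate`), `variance_pct`, `loadings`, and `load_genes`
#'   (per component: `top`, `bottom` id vectors).
#' @export
pca_map <- function(expr, genes = NULL, n_components = 3,
                    load_fraction = 0.05, standardize = TRUE) {
  expr <- as_tibble(expr)
  check_columns(expr, c("gene_id", "sample_id", "replicate", "rpm"), "expr")
  if (!is.null(genes)) expr <- filter(expr, .data$gene_id %in% genes)
  wide <- expr %>%
    select("gene_id", "sample_id", "replicate", "rpm") %>%
    tidyr::pivot_wider(names_from = "gene_id", values_from = "rpm")
  obs <- select(wide, "sample_id", "replicate")
  m <- as.matrix(wide[, -(1:2)])
  if (nrow(m) < 3) {
    ptj_abort("need >= 3 libraries for a PCA map.", "ptj_error_argument")
  }
  sds <- apply(m, 2, sd)
  keep <- sds > 0
  m <- m[, keep, drop = FALSE]
  if (ncol(m) < 2) {
    ptj_abort("degenerate matrix: fewer than 2 variable genes.",
              "ptj_error_argument")
  }
  pc <- prcomp(m, center = TRUE, scale. = standardize)
  n_components <- min(n_components, ncol(pc$x))
  variance_pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  n_tail <- ceiling(load_fraction * ncol(m))
  load_genes <- lapply(seq_len(n_components), function(j) {
    ord <- order(pc$rotation[, j], decreasing = TRUE)
    ids <- rownames(pc$rotation)
    list(top = ids[ord[seq_len(n_tail)]],
         bottom = ids[rev(ord)[seq_len(n_tail)]])
  })
  names(load_genes) <- paste0("PC", seq_len(n_components))
  structure(
    list(
      scores = dplyr::bind_cols(
        obs, as_tibble(pc$x[, seq_len(n_components), drop = FALSE])),
      variance_pct = variance_pct,
      loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
      load_genes = load_genes,
      n_components = n_components
    ),
    class = "ptj_pca"
  )
}

#' @export
print.ptj_pca <- function(x, ...) {
  cat("<ptj_pca>\n")
  cat(sprintf("  %d libraries; variance: %s\n", nrow(x$scores),
              paste(sprintf("PC%d %.1f%%", seq_len(x$n_components),
                            x$variance_pct[seq_len(x$n_components)]),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname pca_map
#' @param x,object A `ptj_pca` object.
#' @param ... Unused.
#' @method glance ptj_pca
#' @export
glance.ptj_pca <- function(x, ...) {
  tibble(
    n_libraries = nrow(x$scores),
    n_genes = nrow(x$loadings),
    variance_pc1 = x$variance_pct[1],
    variance_pc2 = x$variance_pct[2],
    variance_pc3 = x$variance_pct[3],
    variance_first3 = sum(x$variance_pct[1:3])
  )
}

#' @rdname pca_map
#' @method autoplot ptj_pca
#' @export
autoplot.ptj_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2,
                               colour = factor(.data$sample_id))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$variance_pct[1]),
      y = sprintf("PC2 (%.1f%%)", object$variance_pct[2]),
      colour = "sample") +
    ggplot2::theme_minimal()
}
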