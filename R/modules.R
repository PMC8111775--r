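#' Weighted co-expression modules ordered by peak timing
#'
#' WGCNA-style module detection on Z-scored profiles of dynamic genes: a
#' soft-thresholded adjacency (`|cor|^beta`, unsigned, or
#' `((1 + cor)/2)^beta`, signed), the topological-overlap measure (TOM) as
#' similarity, average-linkage hierarchical clustering of the TOM
#' dissimilarity, and a fixed-size tree cut. Modules are relabelled 1..k by
#' the timing of their mean-profile peak so module 1 peaks earliest along
#' the gradient.
#'
#' @param z A numeric matrix of Z-scored profiles, genes in rows (named),
#'   samples in ordered columns (see [zscore_profiles()]).
#' @param soft_power Soft-threshold exponent beta (default 14).
#' @param n_modules Number of modules to cut the tree into (default 12).
#' @param network_type `"unsigned"` (default) uses `|cor|`; `"signed"` uses
#'   `(1 + cor)/2`, keeping anti-correlated genes apart.
#' @return A `ptj_modules` object with `assignment` (tibble `gene_id`,
#'   `module`, `peak_sample`), `module_peaks` (tibble `module`,
#'   `peak_sample`, `n_genes`), `tree` (the hclust), and the call
#'   parameters.
#' @export
cluster_modules <- function(z, soft_power = 14, n_modules = 12,
                            network_type = c("unsigned", "signed")) {
  network_type <- match.arg(network_type)
  if (!is.matrix(z) || nrow(z) < 2) {
    ptj_abort("`z` must be a matrix with >= 2 gene rows.",
              "ptj_error_argument")
  }
  check_number(soft_power, "soft_power", lower = 1)
  if (any(apply(z, 1, sd) == 0)) {
    ptj_abort("constant gene rows cannot be clustered; run the DYG filter first.",
              class = "ptj_error_constant")
  }
  n_modules <- min(n_modules, nrow(z))
  cc <- cor(t(z))
  adj <- if (network_type == "unsigned") abs(cc)^soft_power else
    ((1 + cc) / 2)^soft_power
  diag(adj) <- 0
  # Topological overlap: shared-neighbour weight relative to the sparser node.
  l <- adj %*% adj
  k <- rowSums(adj)
  kmin <- outer(k, k, pmin)
  tom <- (l + adj) / (kmin + 1 - adj)
  diag(tom) <- 1
  diss <- 1 - tom
  tree <- hclust(stats::as.dist(diss), method = "average")
  raw <- cutree(tree, k = n_modules)

  peaks <- peak_sample(z)
  module_peak <- tapply(peaks, raw, function(p) median(p))
  # Relabel so module ids follow non-decreasing peak timing.
  ord <- order(module_peak, as.numeric(names(module_peak)))
  relabel <- setNames(seq_along(ord), names(module_peak)[ord])
  module <- unname(relabel[as.character(raw)])

  assignment <- tibble(gene_id = rownames(z), module = module,
                       peak_sample = unname(peaks)) %>%
    arrange(.data$module, .data$gene_id)
  module_peaks <- assignment %>%
    group_by(.data$module) %>%
    summarise(peak_sample = median(.data$peak_sample),
              n_genes = dplyr::n(), .groups = "drop")
  structure(
    list(assignment = assignment, module_peaks = module_peaks, tree = tree,
         soft_power = soft_power, n_modules = n_modules,
         network_type = network_type, z = z),
    class = "ptj_modules"
  )
}

#' @export
print.ptj_modules <- function(x, ...) {
  cat(sprintf("<ptj_modules> %d genes in %d modules (%s, beta = %g)\n",
              nrow(x$assignment), x$n_modules, x$network_type, x$soft_power))
  print(x$module_peaks, n = Inf)
  invisible(x)
}

#' @rdname cluster_modules
#' @param x,object A `ptj_modules` object.
#' @param ... Unused.
#' @method tidy ptj_modules
#' @export
tidy.ptj_modules <- function(x, ...) x$assignment

#' @rdname cluster_modules
#' @method glance ptj_modules
#' @export
glance.ptj_modules <- function(x, ...) {
  tibble(n_genes = nrow(x$assignment), n_modules = x$n_modules,
         soft_power = x$soft_power, network_type = x$network_type)
}

#' @rdname cluster_modules
#' @method autoplot ptj_modules
#' @export
autoplot.ptj_modules <- function(object, ...) {
  ord <- arrange(object$assignment, .data$module, .data$peak_sample)
  df <- as_tibble(object$z[ord$gene_id, , drop = FALSE], rownames = "gene_id") %>%
    mutate(row = row_number()) %>%
    tidyr::pivot_longer(cols = -c("gene_id", "row"),
                        names_to = "sample_id", values_to = "z") %>%
    mutate(sample_id = as.numeric(.data$sample_id))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$row,
                                   fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "sample", y = "genes (module-ordered)", fill = "Z") +
    ggplot2::theme_minimal()
}

#' Hypergeometric over/under-representation of a gene class in a module
#'
#' Exact hypergeometric tail probabilities of the observed overlap between a
#' module's gene set and a functional class within a common gene universe.
#' The over-representation p-value is the upper tail (P[X >= overlap]) and
#' the under-representation p-value the lower tail (P[X <= overlap]); both
#' are reported raw together with their -log10.
#'
#' @param module_genes,class_genes Character vectors of gene ids, both
#'   subsets of `universe`.
#' @param universe Character vector of all eligible gene ids.
#' @return A one-row tibble: `overlap`, `module_size`, `class_size`,
#'   `universe_size`, `expected`, `p_over`, `p_under`, `neg_log10_over`,
#'   `neg_log10_under`.
#' @export
#' @examples
#' enrich_overlap(letters[1:5], letters[1:5], letters[1:20])
enrich_overlap <- function(module_genes, class_genes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) {
    ptj_abort("`universe` is empty.", "ptj_error_argument")
  }
  module_genes <- intersect(unique(module_genes), universe)
  class_genes <- intersect(unique(class_genes), universe)
  k <- length(intersect(module_genes, class_genes))
  m <- length(class_genes)
  n <- length(universe) - m
  s <- length(module_genes)
  p_over <- phyper(k - 1, m, n, s, lower.tail = FALSE)
  p_under <- phyper(k, m, n, s, lower.tail = TRUE)
  tibble(
    overlap = k, module_size = s, class_size = m,
    universe_size = length(universe),
    expected = s * m / length(universe),
    p_over = p_over, p_under = p_under,
    neg_log10_over = -log10(p_over), neg_log10_under = -log10(p_under)
  )
}

#' Enrichment of every functional class in every module
#'
#' @param modules A `ptj_modules` object or a data frame with `gene_id`,
#'   `module`.
#' @param annotation A data frame with `gene_id`, `class`.
#' @param universe Gene universe (default: all annotated clustered genes).
#' @param adjust Add Benjamini-Hochberg adjusted columns (default FALSE,
#'   matching the raw -log10 display convention).
#' @return A tibble with one row per module x class and the
#'   [enrich_overlap()] columns.
#' @export
enrich_modules <- function(modules, annotation, universe = NULL,
                           adjust = FALSE) {
  assignment <- if (inherits(modules, "ptj_modules")) modules$assignment
  else as_tibble(modules)
  check_columns(assignment, c("gene_id", "module"), "modules")
  annotation <- as_tibble(annotation)
  check_columns(annotation, c("gene_id", "class"), "annotation")
  universe <- universe %||% union(assignment$gene_id, annotation$gene_id)
  out <- tidyr::expand_grid(
    module = sort(unique(assignment$module)),
    class = sort(unique(annotation$class))
  )
  res <- purrr::pmap(out, function(module, class) {
    enrich_overlap(
      assignment$gene_id[assignment$module == module],
      annotation$gene_id[annotation$class == class],
      universe)
  })
  out <- dplyr::bind_cols(out, dplyr::bind_rows(res))
  if (adjust) {
    out$p_over_bh <- p.adjust(out$p_over, method = "BH")
    out$p_under_bh <- p.adjust(out$p_under, method = "BH")
  }
  out
}
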