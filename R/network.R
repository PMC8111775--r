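#' Assemble network targets: dynamic genes for chloroplast-targeted proteins
#'
#' Intersects the dynamically expressed gene set with the genes flagged as
#' encoding plastid-localised proteins, and removes any gene that is itself a
#' candidate regulator.
#'
#' @param dyg Character vector of dynamic gene ids (e.g.
#'   `attr(dyg_filter(expr), "dyg")`).
#' @param annotation A data frame with `gene_id` and logical
#'   `plastid_localized`.
#' @param regulators Character vector of regulator gene ids to exclude.
#' @return Character vector of target gene ids.
#' @export
assemble_targets <- function(dyg, annotation, regulators = character()) {
  annotation <- as_tibble(annotation)
  check_columns(annotation, c("gene_id", "plastid_localized"), "annotation")
  flagged <- annotation$gene_id[annotation$plastid_localized %in% TRUE]
  targets <- setdiff(intersect(dyg, flagged), regulators)
  if (length(targets) == 0) {
    ptj_abort("no targets: the dynamic set and the plastid-localised flags do not intersect.",
              class = "ptj_error_empty_targets")
  }
  targets
}

#' Tree-ensemble regulator ranking
#'
#' For each target gene, an ensemble of regression trees (a random forest
#' with square-root feature subsampling) predicts the target's expression
#' profile from the candidate regulators' profiles; the total
#' variance-reduction (impurity) importance credited to each regulator,
#' normalised per target to sum to 1, is the regulatory weight. Targets with
#' a constant profile carry no signal and receive an all-zero, flagged row.
#' Results are deterministic under a fixed seed and invariant to regulator
#' column order (regulators are sorted internally before fitting).
#'
#' @param expr_matrix Numeric matrix of expression observations x genes
#'   (rows are e.g. the 45 Z-scored sample x replicate libraries), columns
#'   named by gene id, containing all targets and regulators. See
#'   [network_observations()].
#' @param targets,regulators Character vectors of column names.
#' @param n_trees Trees per ensemble (default 1000).
#' @param seed Integer seed controlling all ensembles.
#' @return A `ptj_ranking` object with `importance` (targets x regulators
#'   matrix, rows summing to 1 or flagged 0), `ranks` (per-target rank of
#'   each regulator, 1 = strongest; NA where importance is 0), and
#'   `no_signal` (logical per target).
#' @export
rank_regulators <- function(expr_matrix, targets, regulators,
                            n_trees = 1000, seed = 1) {
  if (!is.matrix(expr_matrix) || is.null(colnames(expr_matrix))) {
    ptj_abort("`expr_matrix` must be a column-named matrix (observations x genes).",
              "ptj_error_argument")
  }
  regulators <- sort(unique(regulators))
  targets <- unique(targets)
  missing <- setdiff(c(targets, regulators), colnames(expr_matrix))
  if (length(missing) > 0) {
    ptj_abort(sprintf("gene(s) absent from `expr_matrix`: %s.",
                      paste(head(missing, 5), collapse = ", ")),
              "ptj_error_argument")
  }
  if (length(regulators) < 2) {
    ptj_abort("need >= 2 candidate regulators.", "ptj_error_argument")
  }
  if (nrow(expr_matrix) < 5) {
    ptj_abort("need >= 5 observations per gene.", "ptj_error_argument")
  }
  x_all <- expr_matrix[, regulators, drop = FALSE]
  mtry <- max(1L, floor(sqrt(length(regulators))))
  imp <- matrix(0, nrow = length(targets), ncol = length(regulators),
                dimnames = list(targets, regulators))
  no_signal <- setNames(logical(length(targets)), targets)
  for (i in seq_along(targets)) {
    tg <- targets[i]
    y <- expr_matrix[, tg]
    if (sd(y) == 0) {
      no_signal[i] <- TRUE
      next
    }
    x <- x_all[, setdiff(regulators, tg), drop = FALSE]
    set.seed(substream_seed(seed, i))
    rf <- randomForest::randomForest(
      x = x, y = y, ntree = n_trees, mtry = min(mtry, ncol(x)),
      importance = FALSE)
    w <- rf$importance[, "IncNodePurity"]
    if (sum(w) > 0) imp[i, names(w)] <- w / sum(w)
  }
  ranks <- t(apply(imp, 1, function(r) {
    rk <- rep(NA_real_, length(r))
    nz <- r > 0
    rk[nz] <- rank(-r[nz], ties.method = "first")
    rk
  }))
  dimnames(ranks) <- dimnames(imp)
  structure(
    list(importance = imp, ranks = ranks, no_signal = no_signal,
         n_trees = n_trees, seed = seed),
    class = "ptj_ranking"
  )
}

#' Build the observations-by-genes matrix for network inference
#'
#' Z-scores each gene across all sample x replicate libraries and returns
#' the observations x genes matrix the tree ensembles consume. With
#' `use_replicates = FALSE` the replicate-averaged per-sample profiles are
#' used instead (fewer observations).
#'
#' @inheritParams rpm_sample_means
#' @param genes Optional subset of gene ids.
#' @param use_replicates Use every library as an observation (default TRUE).
#' @return Numeric matrix, observations x genes.
#' @export
network_observations <- function(expr, genes = NULL, use_replicates = TRUE) {
  expr <- as_tibble(expr)
  check_columns(expr, c("gene_id", "sample_id", "rpm"), "expr")
  if (!is.null(genes)) expr <- filter(expr, .data$gene_id %in% genes)
  if (use_replicates) {
    check_columns(expr, "replicate", "expr")
    wide <- expr %>%
      select("gene_id", "sample_id", "replicate", "rpm") %>%
      tidyr::pivot_wider(names_from = "gene_id", values_from = "rpm") %>%
      arrange(.data$sample_id, .data$replicate)
    m <- as.matrix(wide[, -(1:2)])
  } else {
    m <- t(rpm_sample_means(expr))
  }
  sds <- apply(m, 2, sd)
  scale(m, center = TRUE, scale = ifelse(sds > 0, sds, 1))
}

#' @export
print.ptj_ranking <- function(x, ...) {
  cat(sprintf("<ptj_ranking> %d targets x %d regulators (%d trees, seed %d)\n",
              nrow(x$importance), ncol(x$importance), x$n_trees, x$seed))
  if (any(x$no_signal)) {
    cat(sprintf("  %d constant target(s) flagged no-signal\n",
                sum(x$no_signal)))
  }
  invisible(x)
}

#' @rdname rank_regulators
#' @param x,object A `ptj_ranking` object.
#' @param ... Unused.
#' @method tidy ptj_ranking
#' @export
tidy.ptj_ranking <- function(x, ...) {
  as_tibble(x$importance, rownames = "target") %>%
    tidyr::pivot_longer(cols = -"target", names_to = "regulator",
                        values_to = "importance") %>%
    left_join(
      as_tibble(x$ranks, rownames = "target") %>%
        tidyr::pivot_longer(cols = -"target", names_to = "regulator",
                            values_to = "rank"),
      by = c("target", "regulator"))
}

#' @rdname rank_regulators
#' @method autoplot ptj_ranking
#' @export
autoplot.ptj_ranking <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$regulator, .data$target,
                                   fill = .data$importance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "grey92", high = "darkgreen",
                                 na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Aggregate regulator importance by developmental phase
#'
#' Averages each regulator's normalised importance over the targets whose
#' co-expression module peaks in each phase, giving a per-phase view of
#' which regulators are predicted to act during plastid vs chloroplast
#' build-up.
#'
#' @param ranking A [rank_regulators()] result.
#' @param modules A `ptj_modules` object or data frame with `gene_id`,
#'   `module`.
#' @param phase_of_module Named vector or data frame (`module`, `phase`)
#'   mapping module ids to phase labels.
#' @return A tibble `phase` x `regulator` with `mean_importance` and
#'   `n_targets`.
#' @export
summarize_by_phase <- function(ranking, modules, phase_of_module) {
  if (!inherits(ranking, "ptj_ranking")) {
    ptj_abort("`ranking` must be a `ptj_ranking`.", "ptj_error_argument")
  }
  assignment <- if (inherits(modules, "ptj_modules")) modules$assignment
  else as_tibble(modules)
  check_columns(assignment, c("gene_id", "module"), "modules")
  if (is.data.frame(phase_of_module)) {
    check_columns(phase_of_module, c("module", "phase"), "phase_of_module")
    ph <- setNames(phase_of_module$phase, phase_of_module$module)
  } else {
    ph <- phase_of_module
  }
  targets <- rownames(ranking$importance)
  mod <- assignment$module[match(targets, assignment$gene_id)]
  if (anyNA(mod)) {
    ptj_abort(sprintf("target(s) without module assignment: %s.",
                      paste(head(targets[is.na(mod)], 3), collapse = ", ")),
              class = "ptj_error_unlabeled")
  }
  phase <- unname(ph[as.character(mod)])
  if (anyNA(phase)) {
    ptj_abort("module(s) without phase label.", "ptj_error_unlabeled")
  }
  as_tibble(ranking$importance, rownames = "target") %>%
    mutate(phase = phase) %>%
    tidyr::pivot_longer(cols = -c("target", "phase"),
                        names_to = "regulator", values_to = "importance") %>%
    group_by(.data$phase, .data$regulator) %>%
    summarise(mean_importance = mean(.data$importance),
              n_targets = dplyr::n_distinct(.data$target),
              .groups = "drop")
}
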