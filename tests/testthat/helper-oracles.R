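# Shared fixtures and independent oracles, built in code at test time.

# Brute-force lineage simulation: an explicit population of cells, each
# carrying plastids. Over one transition each plastid divides with
# probability p_org (organelle proliferation) and a fraction p_div of cells
# divides, splitting plastids binomially between the daughters. Returns the
# mean per-cell plastid count before and after, and the realised correction
# factor. Independent of the rate formulas under test.
simulate_lineage <- function(n_cells, n0_mean, p_org, p_div, seed) {
  set.seed(seed)
  plastids <- rpois(n_cells, n0_mean)
  plastids <- pmax(plastids, 1)
  mean_before <- mean(plastids)
  # organelle divisions
  plastids <- plastids + rbinom(n_cells, plastids, p_org)
  # cell divisions: dividing cells are replaced by two daughters
  divides <- runif(n_cells) < p_div
  daughters_a <- rbinom(sum(divides), plastids[divides], 0.5)
  daughters_b <- plastids[divides] - daughters_a
  plastids <- c(plastids[!divides], daughters_a, daughters_b)
  list(
    mean_before = mean_before,
    mean_after = mean(plastids),
    correction = length(plastids) / n_cells,
    true_org_rounds = log2(1 + p_org)
  )
}

# Tiny long-format count table: genes x samples x replicates from a matrix
# of per-sample true counts (replicated exactly, no noise).
make_count_table <- function(mat, n_reps = 3) {
  stopifnot(!is.null(rownames(mat)))
  tidyr::expand_grid(
    gene_id = rownames(mat),
    sample_id = seq_len(ncol(mat)),
    replicate = seq_len(n_reps)
  ) |>
    dplyr::mutate(count = mat[cbind(match(gene_id, rownames(mat)),
                                    sample_id)])
}

# Small default simulation reused across tests (cheap: few genes).
small_sim <- function(seed = 1, ...) {
  simulate_experiment(sim_config(seed = seed, n_genes = 80, ...))
}
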