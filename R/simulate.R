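#' Simulate a complete leaf-gradient experiment with planted ground truth
#'
#' Generates every input stream of the pipeline from one configuration:
#' the ordered sample frame, per-cell microscopy measurements following a
#' planted biphasic organelle trajectory, flow-cytometry cell-cycle
#' fractions with a declining S-phase profile, qPCR standard curves and
#' unknowns encoding planted plastid-genome copy numbers, 16S/18S rRNA
#' quantities, and a module-structured expression matrix with
#' negative-binomial replicate noise and planted regulator-to-target
#' dependencies. The returned ground truth makes every downstream estimate
#' checkable.
#'
#' All tables share sample ids; every random block draws from a substream
#' seed derived from `config$seed` by a fixed offset, so regenerating one
#' table never perturbs the others and a fixed seed yields byte-identical
#' output.
#'
#' @param config A [sim_config()] object.
#' @return A `ptj_sim` list: `config`, `sample_frame`, `cells`,
#'   `cell_cycle`, `qpcr`, `rrna`, `expression`, `annotation`,
#'   `ground_truth`.
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 60, seed = 7))
#' sim$ground_truth$phase_boundary_sample
simulate_experiment <- function(config = sim_config()) {
  if (!inherits(config, "ptj_sim_config")) {
    ptj_abort("invalid configuration: `config` must come from sim_config().",
              class = "ptj_error_config")
  }
  sample_frame <- sim_sample_frame(config)
  truth <- sim_truth_trajectories(config, sample_frame)
  cell_cycle <- sim_cell_cycle(config, truth)
  cells <- sim_cells(config, truth)
  qpcr <- sim_qpcr(config, truth)
  rrna <- sim_rrna(config, truth)
  exprs <- sim_expression(config, sample_frame)

  ground_truth <- c(truth["sample_truth"], truth["transition_truth"],
                    list(
                      phase_boundary_sample = truth$phase_boundary_sample,
                      organelle_rounds_total = config$organelle_rounds_total,
                      gene_modules = exprs$gene_modules,
                      planted_edges = exprs$planted_edges,
                      regulators = exprs$regulators,
                      true_profiles = exprs$true_profiles,
                      module_peak_samples = config$module_peak_samples,
                      seed = config$seed
                    ))
  structure(
    list(config = config, sample_frame = sample_frame, cells = cells,
         cell_cycle = cell_cycle, qpcr = qpcr, rrna = rrna,
         expression = exprs$expression, annotation = exprs$annotation,
         ground_truth = ground_truth),
    class = "ptj_sim"
  )
}

#' @export
print.ptj_sim <- function(x, ...) {
  cat("<ptj_sim>\n")
  cat(sprintf("  %d samples x %d replicates, %d genes, %d cells/sample, seed %d\n",
              x$config$n_samples, x$config$n_replicates, x$config$n_genes,
              x$config$n_cells_per_sample, x$config$seed))
  invisible(x)
}

# ---- sample frame ---------------------------------------------------------

sim_sample_frame <- function(config, mature_age_days = 8) {
  starts <- c(0, 0, 5, 10, 15, 20, 25, 30, 35, 45, 60, 75, 90, 105, NA)
  ends <- c(0, 5, 10, 15, 20, 25, 30, 35, 40, 55, 70, 85, 100, 115, NA)
  mids <- (starts + ends) / 2
  am <- age_model()
  ages <- c(position_to_age(mids[1:14], am), mature_age_days)
  tibble(
    sample_id = 1:15,
    start_mm = starts,
    end_mm = ends,
    midpoint_mm = mids,
    age_days = ages,
    under_coleoptile = c(rep(TRUE, 8), rep(FALSE, 7)),
    continuous = c(rep(TRUE, 9), rep(FALSE, 5), NA),
    mature = c(rep(FALSE, 14), TRUE)
  )
}

# ---- planted trajectories -------------------------------------------------

# The planted per-transition series: organelle division rounds d_i peaking
# early (summing to organelle_rounds_total by the end of the plastid phase),
# a per-plastid area growth series delta_a_i with a second hump at the
# chloroplast-phase anchor, and the S-phase decline that drives the
# cell-division correction. All are deterministic given the config.
sim_truth_trajectories <- function(config, sample_frame) {
  n <- config$n_samples
  nt <- n - 1
  ages <- sample_frame$age_days
  dt <- diff(ages)
  p1 <- config$biphasic_params[1]
  trough <- config$biphasic_params[2]
  p2 <- config$biphasic_params[3]

  # S-phase fraction: full cycling at the apex, ~0 by sample 4.
  f_rel <- c(1, 0.8, 0.267, 0.027, 0.02, 0.017, 0.013, 0.012, 0.010,
             0.008, 0.007, 0.007, 0.006, 0.006, 0.006)
  f_s <- config$s_phase_start * f_rel[seq_len(n)]
  corr <- correction_factor(f_s[-n], f_s[1])
  cell_rounds <- log2(corr)

  # Organelle division rounds: early activity scaled to the configured
  # total, quiescence to the trough, then a small late decline.
  d <- numeric(nt)
  active <- seq_len(p1 + 1)
  w <- 1.3 * (1 - 0.2 * pmax(0, active - (p1 - 1)))
  d[active] <- w / sum(w) * config$organelle_rounds_total
  late <- seq_len(nt) > trough + 1
  d[late] <- -0.05

  # Per-plastid area growth (log2 rounds per transition).
  delta_a <- numeric(nt)
  delta_a[seq_len(p1 + 1)] <- 0.12
  if (trough - 1 >= p1 + 2) {
    mid <- seq(p1 + 2, trough - 1)
    frac <- (trough - mid) / (trough - p1 - 2)
    delta_a[mid] <- 0.06 + 0.44 * frac^1.5
  }
  lateidx <- seq(trough, nt)
  delta_a[lateidx] <- 0.06 + 0.64 * exp(-((lateidx - p2) / 1.6)^2)

  n_plastids <- 10 * 2^c(0, cumsum(d - cell_rounds))
  plastid_area <- 2 * 2^c(0, cumsum(delta_a))
  cell_area <- c(150, 190, 260, 360, 480, 620, 780, 950, 1130, 1350,
                 1570, 1800, 2000, 2200, 2400)[seq_len(n)]

  cpdna <- c(25, 30, 45, 70, 95, 110, 120, 128, 135, 140, 145, 148,
             148, 146, 142)[seq_len(n)]
  rrna <- c(0.008, 0.010, 0.020, 0.050, 0.100, 0.150, 0.200, 0.240,
            0.270, 0.290, 0.300, 0.310, 0.310, 0.305, 0.295)[seq_len(n)]

  sample_truth <- tibble(
    sample_id = sample_frame$sample_id,
    age_days = ages,
    f_s_true = f_s,
    n_plastids_true = n_plastids,
    plastid_area_true = plastid_area,
    cell_area_true = cell_area,
    total_plastid_area_true = n_plastids * plastid_area,
    cpdna_ratio_true = cpdna,
    rrna_ratio_true = rrna,
    cum_organelle_rounds_true = c(0, cumsum(d)),
    cum_cell_rounds_true = c(0, cumsum(cell_rounds))
  )
  transition_truth <- tibble(
    from_sample = seq_len(nt),
    to_sample = seq_len(nt) + 1L,
    dt_days = dt,
    organelle_rounds = d,
    cell_rounds = cell_rounds,
    correction_true = corr,
    delta_area = delta_a,
    division_rate_true = d / dt,
    growth_rate_true = (d + delta_a) / dt
  )
  list(sample_truth = sample_truth, transition_truth = transition_truth,
       phase_boundary_sample = trough)
}

# ---- flow cytometry -------------------------------------------------------

sim_cell_cycle <- function(config, truth) {
  set.seed(substream_seed(config$seed, 11L))
  st <- truth$sample_truth
  n <- nrow(st)
  f_g2 <- c(0.15, 0.13, 0.10, 0.07, 0.05, 0.04, 0.03, 0.03, 0.025,
            0.02, 0.02, 0.02, 0.02, 0.02, 0.02)[seq_len(n)]
  background <- 0.03
  purrr::map_dfr(seq_len(n), function(i) {
    n_nuclei <- 10000L + stats::rpois(1, 2000)
    p <- c(g1 = 1 - st$f_s_true[i] - f_g2[i] - background,
           s = st$f_s_true[i], g2 = f_g2[i], bg = background)
    counts <- drop(rmultinom(1, n_nuclei, p))
    tibble(sample_id = st$sample_id[i],
           f_g1 = counts[1] / n_nuclei,
           f_s = counts[2] / n_nuclei,
           f_g2 = counts[3] / n_nuclei,
           n_nuclei = n_nuclei)
  })
}

# ---- microscopy -----------------------------------------------------------

# Lognormal cell-to-cell variation with meanlog shifted by -sd^2/2 so the
# arithmetic sample mean is unbiased for the planted value.
rlnorm_mean <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

sim_cells <- function(config, truth) {
  set.seed(substream_seed(config$seed, 12L))
  st <- truth$sample_truth
  reps <- config$n_replicates
  per_rep <- diff(round(seq(0, config$n_cells_per_sample,
                            length.out = reps + 1)))
  purrr::map_dfr(seq_len(nrow(st)), function(i) {
    purrr::map_dfr(seq_len(reps), function(r) {
      k <- per_rep[r]
      tibble(
        sample_id = st$sample_id[i],
        replicate = r,
        cell_id = sprintf("S%02dR%dC%02d", st$sample_id[i], r, seq_len(k)),
        cell_area = rlnorm_mean(k, st$cell_area_true[i],
                                config$cell_area_cv),
        plastid_count = pmax(1, round(rlnorm_mean(
          k, st$n_plastids_true[i], config$plastid_count_cv))),
        mean_plastid_area = rlnorm_mean(k, st$plastid_area_true[i],
                                        config$plastid_area_cv)
      )
    })
  })
}

# ---- qPCR -----------------------------------------------------------------

sim_qpcr <- function(config, truth, n_biological = 3, n_technical = 2) {
  set.seed(substream_seed(config$seed, 13L))
  st <- truth$sample_truth
  eff <- config$qpcr_efficiencies
  slopes <- -1 / log10(1 + eff)
  intercepts <- c(rbcL = 14, ndhD = 14.5, rps7 = 13.8, TaKO1 = 21,
                  TaKS = 21.5)
  dilution <- c(rbcL = 100, ndhD = 100, rps7 = 100, TaKO1 = 10, TaKS = 10)
  concs <- 10^seq(log10(config$standard_range[1]),
                  log10(config$standard_range[2]), length.out = 5)

  standards <- tidyr::expand_grid(
    amplicon = names(eff), concentration = concs,
    technical = seq_len(n_technical)) %>%
    mutate(
      role = "standard", sample_id = NA_integer_, biological = NA_integer_,
      dilution_factor = 1,
      cq = intercepts[.data$amplicon] +
        slopes[.data$amplicon] * log10(.data$concentration) +
        rnorm(dplyr::n(), sd = config$cq_sd_standard)
    )

  unknowns <- tidyr::expand_grid(
    sample_id = st$sample_id, biological = seq_len(n_biological)) %>%
    mutate(nuclear_pg = rlnorm_mean(dplyr::n(), 6, 0.15))
  unknowns <- tidyr::expand_grid(
    unknowns, amplicon = names(eff), technical = seq_len(n_technical)) %>%
    mutate(
      ratio = st$cpdna_ratio_true[match(.data$sample_id, st$sample_id)],
      true_quantity = dplyr::case_when(
        .data$amplicon %in% c("TaKO1", "TaKS") ~ .data$nuclear_pg,
        .data$amplicon == "rps7" ~ 2 * .data$ratio * .data$nuclear_pg,
        TRUE ~ .data$ratio * .data$nuclear_pg
      ),
      role = "unknown", concentration = NA_real_,
      dilution_factor = dilution[.data$amplicon],
      cq = intercepts[.data$amplicon] + slopes[.data$amplicon] *
        log10(.data$true_quantity / .data$dilution_factor) +
        rnorm(dplyr::n(), sd = config$cq_sd)
    ) %>%
    select(-"nuclear_pg", -"ratio", -"true_quantity")

  bind_rows(
    select(standards, "amplicon", "role", "concentration", "sample_id",
           "biological", "technical", "dilution_factor", "cq"),
    select(unknowns, "amplicon", "role", "concentration", "sample_id",
           "biological", "technical", "dilution_factor", "cq")
  )
}

# ---- rRNA -----------------------------------------------------------------

sim_rrna <- function(config, truth, n_biological = 3, n_technical = 2) {
  set.seed(substream_seed(config$seed, 14L))
  st <- truth$sample_truth
  bio <- tidyr::expand_grid(sample_id = st$sample_id,
                            biological = seq_len(n_biological)) %>%
    mutate(
      q18 = rlnorm_mean(dplyr::n(), 100, 0.2),
      q16 = st$rrna_ratio_true[match(.data$sample_id, st$sample_id)] *
        .data$q18 * rlnorm_mean(dplyr::n(), 1, 0.08)
    )
  tidyr::expand_grid(bio, target = c("16S", "18S"),
                     technical = seq_len(n_technical)) %>%
    mutate(quantity = ifelse(.data$target == "16S", .data$q16, .data$q18) *
             rlnorm_mean(dplyr::n(), 1, 0.05)) %>%
    select("sample_id", "biological", "technical", "target", "quantity")
}

# ---- expression -----------------------------------------------------------

sim_expression <- function(config, sample_frame) {
  set.seed(substream_seed(config$seed, 15L))
  n <- config$n_samples
  reps <- config$n_replicates
  ages <- sample_frame$age_days
  n_dyn <- round(config$frac_dynamic * config$n_genes)
  n_flat <- config$n_genes - n_dyn
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  dyn_ids <- gene_ids[seq_len(n_dyn)]
  flat_ids <- setdiff(gene_ids, dyn_ids)
  module <- rep_len(seq_len(config$n_modules), n_dyn)

  peak_age <- ages[config$module_peak_samples]
  sigma <- 0.25 + 0.2 * peak_age
  bump <- function(peak, sig) exp(-(ages - peak)^2 / (2 * sig^2))

  baseline <- runif(n_dyn, 0.5, 3)
  amplitude <- pmax(10, rlnorm(n_dyn, log(40), 0.5))
  dyn_profiles <- t(vapply(seq_len(n_dyn), function(g) {
    baseline[g] + amplitude[g] * bump(peak_age[module[g]], sigma[module[g]])
  }, numeric(n)))
  flat_level <- pmin(200, pmax(0.2, rlnorm(n_flat, log(8), 1.2)))
  flat_profiles <- matrix(flat_level, nrow = n_flat, ncol = n)

  panel <- default_regulator_panel()
  reg_ids <- paste0("REG_", panel$regulator)
  reg_sigma <- 0.25 + 0.2 * ages[panel$peak_sample]
  reg_profiles <- t(vapply(seq_len(nrow(panel)), function(r) {
    1 + 50 * bump(ages[panel$peak_sample[r]], reg_sigma[r])
  }, numeric(n)))

  profiles <- rbind(dyn_profiles, flat_profiles, reg_profiles)
  rownames(profiles) <- c(dyn_ids, flat_ids, reg_ids)

  n_lib <- n * reps
  lib_sizes <- rlnorm_mean(n_lib, config$library_size, config$library_cv)
  lib <- tidyr::expand_grid(sample_id = seq_len(n),
                            replicate = seq_len(reps)) %>%
    mutate(lib_size = lib_sizes)

  draw_counts <- function(mu) {
    if (is.infinite(config$nb_dispersion)) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = config$nb_dispersion)
  }
  # counts for all non-target genes; mu indexed per library
  mu <- profiles[, lib$sample_id, drop = FALSE] *
    matrix(lib$lib_size / 1e6, nrow = nrow(profiles), ncol = n_lib,
           byrow = TRUE)
  counts <- matrix(draw_counts(mu), nrow = nrow(profiles),
                   dimnames = list(rownames(profiles), NULL))

  # planted regulator -> target dependencies: overwrite the target's counts
  # so its per-library mean follows the regulator's realised RPM additively
  edges <- config$planted_edges
  n_targets <- nrow(edges)
  if (n_targets > n_dyn) {
    ptj_abort("invalid configuration: `planted_edges` has more rows than there are dynamic genes.",
              class = "ptj_error_config")
  }
  edges$target <- dyn_ids[seq_len(n_targets)]
  reg_rpm <- counts[paste0("REG_", edges$regulator), , drop = FALSE] /
    matrix(lib$lib_size, nrow = n_targets, ncol = n_lib, byrow = TRUE) * 1e6
  for (e in seq_len(n_targets)) {
    mu_t <- (2 + edges$effect[e] * reg_rpm[e, ]) * lib$lib_size / 1e6
    counts[edges$target[e], ] <- draw_counts(mu_t)
    # the target now tracks its regulator's bump; reassign its module to
    # the planted module peaking nearest the regulator's peak sample
    rp <- panel$peak_sample[match(edges$regulator[e],
                                  panel$regulator)]
    module[match(edges$target[e], dyn_ids)] <-
      which.min(abs(config$module_peak_samples - rp))
  }

  # expand_grid varies the library block fastest, so rows stay aligned with
  # the gene-major layout of t(counts)
  expression <- tidyr::expand_grid(
    gene_id = rownames(counts),
    dplyr::select(lib, "sample_id", "replicate"))
  expression$count <- as.vector(t(counts))
  lib_idx <- rep(seq_len(n_lib), times = nrow(counts))
  expression$rpm <- expression$count / lib$lib_size[lib_idx] * 1e6

  gm_ids <- c(dyn_ids, flat_ids, reg_ids)
  gene_modules <- tibble(
    gene_id = gm_ids,
    module = c(module, rep(NA_integer_, n_flat + length(reg_ids))),
    dynamic = c(rep(TRUE, n_dyn), rep(FALSE, n_flat),
                rep(TRUE, length(reg_ids))),
    planted_target = gm_ids %in% edges$target,
    is_regulator = gm_ids %in% reg_ids
  )

  # annotation: module-linked functional classes + plastid localisation
  classes <- c("cell_cycle", "hormone", "translation", "cell_wall",
               "photosynthesis", "other")
  favored <- rep_len(c("cell_cycle", "hormone", "translation", "cell_wall",
                       rep("photosynthesis", 8)), config$n_modules)
  gene_class <- character(config$n_genes)
  for (g in seq_len(config$n_genes)) {
    if (g <= n_dyn) {
      fav <- favored[module[g]]
      gene_class[g] <- if (runif(1) < 0.6) fav else sample(classes, 1)
    } else {
      gene_class[g] <- if (runif(1) < 0.7) "other" else sample(classes, 1)
    }
  }
  peak_of_module <- config$module_peak_samples
  plastid_prob <- ifelse(
    c(rep(TRUE, n_dyn), rep(FALSE, n_flat)) &
      peak_of_module[pmax(c(module, rep(1L, n_flat)), 1L)] >= 6,
    0.35, 0.05)
  plastid_flag <- runif(config$n_genes) < plastid_prob
  plastid_flag[match(edges$target, gene_ids)] <- TRUE
  annotation <- tibble(
    gene_id = c(gene_ids, reg_ids),
    class = c(gene_class, rep("regulator", length(reg_ids))),
    plastid_localized = c(plastid_flag, rep(FALSE, length(reg_ids)))
  )

  regulators <- panel
  regulators$gene_id <- reg_ids

  true_profiles <- as_tibble(profiles, .name_repair = ~ paste0("S", seq_len(n)))
  true_profiles <- dplyr::bind_cols(tibble(gene_id = rownames(profiles)),
                                    true_profiles)

  list(expression = expression, annotation = annotation,
       gene_modules = gene_modules,
       planted_edges = select(edges, "regulator", "target", "effect"),
       regulators = regulators, true_profiles = true_profiles)
}
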