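test_that("invalid configurations fail with the offending field named", {
  expect_error(sim_config(n_samples = 12), regexp = "n_samples",
               class = "ptj_error_config")
  expect_error(sim_config(s_phase_start = 1.2), regexp = "s_phase_start",
               class = "ptj_error_config")
  expect_error(sim_config(nb_dispersion = 0), regexp = "nb_dispersion",
               class = "ptj_error_config")
  expect_error(sim_config(standard_range = c(1, 2)),
               regexp = "standard_range", class = "ptj_error_config")
  expect_error(sim_config(module_peak_samples = c(1, 99),
                          n_modules = 2),
               regexp = "module_peak_samples", class = "ptj_error_config")
})

test_that("a fixed seed reproduces the experiment exactly", {
  s1 <- small_sim(seed = 5)
  s2 <- small_sim(seed = 5)
  for (tb in c("sample_frame", "cells", "cell_cycle", "qpcr", "rrna",
               "expression", "annotation")) {
    expect_identical(s1[[tb]], s2[[tb]], label = tb)
  }
  s3 <- small_sim(seed = 6)
  expect_false(identical(s1$cells, s3$cells))
})

test_that("fixture bundles are byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture_bundle(small_sim(seed = 42), d1)
  write_fixture_bundle(small_sim(seed = 42), d2)
  files <- list.files(d1)
  expect_length(setdiff(c(paste0(
    c("sample_frame", "cells", "cell_cycle", "qpcr", "rrna", "expression",
      "annotation"), ".tsv"), "ground_truth.json", "manifest.json"),
    files), 0)
  for (f in setdiff(files, "manifest.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", n = 1e7),
                     readBin(file.path(d2, f), "raw", n = 1e7), label = f)
  }
})

test_that("bundle round-trip preserves tables and manifest tracks the seed", {
  sim <- small_sim(seed = 9)
  dir <- withr::local_tempdir()
  manifest <- write_fixture_bundle(sim, dir)
  back <- read_fixture_bundle(dir)
  expect_equal(as.data.frame(back$cells), as.data.frame(sim$cells))
  expect_equal(as.data.frame(back$expression),
               as.data.frame(sim$expression))
  expect_equal(back$manifest$seed, 9)
  other <- write_fixture_bundle(small_sim(seed = 10),
                                withr::local_tempdir())
  expect_false(identical(manifest$config_hash, other$config_hash))
})

test_that("planted module means are unimodal with the configured peak", {
  sim <- small_sim(seed = 2)
  gm <- sim$ground_truth$gene_modules
  tp <- sim$ground_truth$true_profiles
  m <- as.matrix(tp[, -1])
  rownames(m) <- tp$gene_id
  peaks <- sim$ground_truth$module_peak_samples
  for (mod in unique(na.omit(gm$module))) {
    ids <- gm$gene_id[!is.na(gm$module) & gm$module == mod &
                        !gm$planted_target & !gm$is_regulator]
    profile <- colMeans(m[ids, , drop = FALSE])
    p <- peaks[mod]
    expect_equal(unname(which.max(profile)), p,
                 label = sprintf("module %d peak", mod))
    # unimodal: no secondary bump rises above a quarter of the range
    rel <- (profile - min(profile)) / diff(range(profile))
    interior <- 2:(length(rel) - 1)
    loc_max <- interior[rel[interior] > rel[interior - 1] &
                          rel[interior] > rel[interior + 1]]
    stray <- setdiff(loc_max, (p - 1):(p + 1))
    expect_true(all(rel[stray] <= 0.25),
                label = sprintf("module %d unimodality", mod))
  }
})

test_that("planted cumulative organelle rounds equal the configured total", {
  cfg <- sim_config(organelle_rounds_total = 4.5, n_genes = 20, seed = 1)
  sim <- simulate_experiment(cfg)
  st <- sim$ground_truth$sample_truth
  trough <- sim$ground_truth$phase_boundary_sample
  expect_equal(st$cum_organelle_rounds_true[trough + 1], 4.5)
  # S phase declines from the configured start to ~0 by sample 4
  expect_equal(st$f_s_true[1], 0.30)
  expect_lt(st$f_s_true[4], 0.01)
})

test_that("infinite dispersion gives Poisson replicate noise (CV ~ 1/sqrt(mean))", {
  sim <- simulate_experiment(sim_config(
    seed = 2, n_genes = 200, nb_dispersion = Inf, library_cv = 0))
  gm <- sim$ground_truth$gene_modules
  special <- gm$gene_id[gm$planted_target | gm$is_regulator]
  vm <- sim$expression |>
    dplyr::filter(!(gene_id %in% special)) |>
    dplyr::group_by(gene_id, sample_id) |>
    dplyr::summarise(m = mean(count), v = var(count), .groups = "drop") |>
    dplyr::filter(m > 200)
  expect_gt(nrow(vm), 100)
  expect_equal(mean(vm$v / vm$m), 1, tolerance = 0.1)
})

test_that("simulated Cq tables refit to the planted standard concentrations", {
  sim <- small_sim(seed = 4)
  q <- sim$qpcr[sim$qpcr$role == "standard", ]
  for (a in unique(q$amplicon)) {
    qa <- q[q$amplicon == a, ]
    curve <- fit_standard_curve(qa, amplicon = a)
    agg <- stats::aggregate(cq ~ concentration, qa, mean)
    est <- absolute_quantity(agg$cq, curve)
    expect_lt(mean(abs(est / agg$concentration - 1)), 0.05)
    expect_equal(curve$efficiency, 0.95, tolerance = 0.05)
  }
})
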