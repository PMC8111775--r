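test_that("RPM normalisation scales each library to one million", {
  counts <- make_count_table(
    matrix(c(1, 3), 2, 3, dimnames = list(c("g1", "g2"), NULL)),
    n_reps = 1)
  rpm <- rpm_normalize(counts)
  expect_equal(sort(unique(rpm$rpm)), c(250000, 750000))
  single <- make_count_table(
    matrix(5, 1, 2, dimnames = list("only", NULL)), n_reps = 1)
  expect_equal(unique(rpm_normalize(single)$rpm), 1e6)
  zero <- make_count_table(
    matrix(0, 1, 1, dimnames = list("g", NULL)), n_reps = 1)
  expect_error(rpm_normalize(zero), regexp = "sample 1 replicate 1",
               class = "ptj_error_library")
})

test_that("expressed filter requires all replicates above 1 RPM somewhere", {
  expr <- tibble::tibble(
    gene_id = rep(c("boundary", "one_low_rep", "silent"), each = 6),
    sample_id = rep(rep(1:2, each = 3), 3),
    replicate = rep(1:3, 6),
    rpm = c(1, 1, 1, 0, 0, 0,       # exactly at threshold in sample 1
            5, 5, 0.5, 5, 5, 0.5,   # always one replicate below
            0, 0, 0, 0, 0, 0)
  )
  expect_equal(expressed_genes(expr), "boundary")
})

test_that("DYG filter applies the three thresholds to sample means", {
  prof <- rbind(
    flat10 = rep(10, 15),
    max_too_low = c(rep(2, 14), 4.9),
    dynamic = c(rep(4, 13), 8, 10),
    switched_off = c(rep(0, 14), 6)
  )
  expr <- make_count_table(prof * 10, n_reps = 3) |>
    dplyr::mutate(rpm = count / 10)
  d <- dyg_filter(expr)
  kept <- attr(d, "dyg")
  expect_setequal(kept, c("dynamic", "switched_off"))
  expect_equal(unname(d$fold_change[d$gene_id == "switched_off"]), Inf)
  expect_equal(unname(d$cv[d$gene_id == "flat10"]), 0)
  # dynamic gene: all three thresholds checked by hand
  row <- d[d$gene_id == "dynamic", ]
  expect_equal(unname(row$max_rpm), 10)
  expect_equal(unname(row$fold_change), 2.5)
  expect_gt(row$cv, 0.2)
})

test_that("filters are idempotent and order independent", {
  sim <- small_sim(seed = 13)
  expr <- sim$expression
  exp1 <- expressed_genes(expr)
  dyg1 <- attr(dyg_filter(expr), "dyg")
  # applying either filter to its own output changes nothing
  expr_sub <- dplyr::filter(expr, gene_id %in% exp1)
  expect_setequal(expressed_genes(expr_sub), exp1)
  expr_dyg <- dplyr::filter(expr, gene_id %in% dyg1)
  expect_setequal(attr(dyg_filter(expr_dyg), "dyg"), dyg1)
  # order: expressed-then-dynamic equals dynamic-within-expressed
  expect_setequal(intersect(dyg1, exp1),
                  attr(dyg_filter(expr_sub), "dyg"))
})

test_that("Z-scoring standardises with the sample-sd convention", {
  z <- zscore_profiles(matrix(c(0, 2), 1, dimnames = list("g", NULL)))
  expect_equal(as.vector(z), c(-1, 1) / sqrt(2))
  m <- matrix(runif(60), 4, 15, dimnames = list(letters[1:4], NULL))
  z2 <- zscore_profiles(m)
  expect_equal(unname(rowMeans(z2)), rep(0, 4))
  expect_equal(unname(apply(z2, 1, sd)), rep(1, 4))
  # affine transforms of the input leave the Z-profile unchanged
  expect_equal(zscore_profiles(3 * m + 7), z2)
  expect_error(zscore_profiles(matrix(1, 2, 5)),
               class = "ptj_error_constant")
})

test_that("peak sample is the earliest argmax", {
  expect_equal(unname(peak_sample(1:10)), 10)
  prof <- c(0, 1, 0, 0, 0, 0, 0, 0, 1, 0)
  expect_equal(unname(peak_sample(prof)), 2)
})

test_that("PCA map sizes the load-factor gene lists at 5% each way", {
  sim <- simulate_experiment(sim_config(seed = 4, n_genes = 100))
  p <- pca_map(sim$expression)
  n_genes <- nrow(p$loadings)
  expect_equal(length(p$load_genes$PC1$top), ceiling(0.05 * n_genes))
  expect_equal(length(p$load_genes$PC1$bottom), ceiling(0.05 * n_genes))
  expect_true(all(diff(p$variance_pct) <= 1e-8))
  expect_lte(sum(p$variance_pct), 100 + 1e-6)
  # duplicated library lands on (nearly) the same score point
  expr <- sim$expression
  dup <- dplyr::mutate(dplyr::filter(expr, sample_id == 1,
                                     replicate == 1), replicate = 99)
  p2 <- pca_map(dplyr::bind_rows(expr, dup))
  sc <- p2$scores
  a <- unlist(sc[sc$sample_id == 1 & sc$replicate == 1, c("PC1", "PC2")])
  b <- unlist(sc[sc$sample_id == 1 & sc$replicate == 99, c("PC1", "PC2")])
  expect_equal(a, b)
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  # all five class members drawn in a five-gene module from 20 genes
  res <- enrich_overlap(letters[1:5], letters[1:5], letters[1:20])
  expect_equal(res$p_over, 1 / choose(20, 5))
  # module equal to the universe forces the overlap: no surprise either way
  full <- enrich_overlap(letters[1:20], letters[1:5], letters[1:20])
  expect_equal(full$p_over, 1)
  # zero overlap where much is expected: depletion, not enrichment
  dep <- enrich_overlap(letters[1:10], letters[11:20], letters[1:20])
  expect_lt(dep$p_under, 1e-4)
  expect_equal(dep$p_over, 1)
  expect_error(enrich_overlap("a", "a", character(0)),
               class = "ptj_error_argument")
})

test_that("variance concentrates in the leading components when planted
           amplitudes dominate noise", {
  # low-rank planted structure, near-noiseless replicates: the first three
  # components must carry >= 60% of the expression variance
  sim <- simulate_experiment(sim_config(
    seed = 5, n_genes = 300, n_modules = 3,
    module_peak_samples = c(2, 8, 14), nb_dispersion = 200))
  p <- pca_map(sim$expression, genes = expressed_genes(sim$expression))
  expect_gte(sum(p$variance_pct[1:3]), 60)
  # at the default 12-module geometry the leading block still dominates
  sim12 <- simulate_experiment(sim_config(seed = 5, n_genes = 300))
  p12 <- pca_map(sim12$expression, genes = expressed_genes(sim12$expression))
  expect_gt(sum(p12$variance_pct[1:3]), 3 * sum(p12$variance_pct[4:6]) / 2)
})
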