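test_that("standard-curve efficiency follows from the slope", {
  # perfect ten-fold series losing 3.3219 cycles per decade: E = 1 exactly
  s <- tibble::tibble(concentration = 10^(1:-3),
                      cq = 15 - 3.321928 * (1:-3))
  curve <- fit_standard_curve(s)
  expect_equal(curve$efficiency, 1, tolerance = 1e-6)
  expect_equal(curve$r_squared, 1)
  # slope -3.6 gives the textbook ~89.6%
  s2 <- tibble::tibble(concentration = 10^(0:-4),
                       cq = 12 - 3.6 * (0:-4))
  expect_equal(fit_standard_curve(s2)$efficiency, 10^(1 / 3.6) - 1)
  expect_error(fit_standard_curve(s[1:2, ]), class = "ptj_error_fit")
})

test_that("refitting a curve on its own predictions is idempotent", {
  s <- tibble::tibble(concentration = 10^seq(1, -3),
                      cq = 14 - 3.45 * seq(1, -3) + rnorm(5, sd = 0.2))
  c1 <- fit_standard_curve(s)
  pred <- tibble::tibble(
    concentration = s$concentration,
    cq = c1$intercept + c1$slope * log10(s$concentration))
  c2 <- fit_standard_curve(pred)
  expect_equal(c2$r_squared, 1)
  expect_equal(c2$slope, c1$slope)
  expect_equal(c2$intercept, c1$intercept)
})

test_that("absolute quantity inverts the curve and applies the dilution", {
  s <- tibble::tibble(concentration = 10^(1:-3),
                      cq = 15 - 3.4 * (1:-3))
  curve <- fit_standard_curve(s)
  expect_equal(absolute_quantity(curve$intercept, curve), 1)
  expect_equal(absolute_quantity(curve$intercept + curve$slope, curve), 10)
  expect_equal(absolute_quantity(20, curve, dilution_factor = 100),
               100 * absolute_quantity(20, curve))
})

test_that("cpDNA formula halves the inverted repeat and is scale invariant", {
  # rps7 sits in the inverted repeat: with rps7 = 2c the ratio reduces to c/n
  expect_equal(cpdna_per_genome(300, 300, 600, 2, 2), 150)
  expect_equal(cpdna_per_genome(300, 270, 630, 2.0, 2.2), 295 / 2.1)
  expect_equal(cpdna_per_genome(0, 0, 0, 2, 2), 0)
  # invariant under common rescaling of all five quantities
  expect_equal(cpdna_per_genome(3, 2.7, 6.3, 0.02, 0.022) ,
               cpdna_per_genome(300, 270, 630, 2.0, 2.2))
  expect_error(cpdna_per_genome(1, 1, 1, 0, 1),
               class = "ptj_error_argument")
})

test_that("rRNA ratio handles boundaries", {
  expect_equal(rrna_ratio(1, 1), 1)
  expect_equal(rrna_ratio(0, 1), 0)
  expect_equal(rrna_ratio(0.25, 1.0), 0.25)
  expect_error(rrna_ratio(1, 0), class = "ptj_error_argument")
})

test_that("replicate aggregation averages technical before biological", {
  one <- aggregate_replicates(3.2)
  expect_true(is.na(one$sem))
  three <- aggregate_replicates(c(1, 2, 3))
  expect_equal(three$mean, 2)
  expect_equal(three$sem, sd(1:3) / sqrt(3))
  # technical pairs (1,3) and (2,2) both average to 2: SEM collapses to 0
  tech <- aggregate_replicates(c(1, 3, 2, 2), c("a", "a", "b", "b"))
  expect_equal(tech$mean, 2)
  expect_equal(tech$sem, 0)
})

test_that("the full qPCR pipeline recovers the planted copy-number series", {
  sim <- small_sim(seed = 8)
  res <- quantify_cpdna(sim$qpcr)
  truth <- sim$ground_truth$sample_truth$cpdna_ratio_true
  expect_equal(res$samples$sample_id, 1:15)
  expect_lt(mean(abs(res$samples$cpdna_mean / truth - 1)), 0.10)
  expect_true(all(vapply(res$curves, function(cv) cv$slope < 0,
                         logical(1))))
  rr <- quantify_rrna(sim$rrna)
  expect_lt(mean(abs(rr$rrna_ratio_mean /
                       sim$ground_truth$sample_truth$rrna_ratio_true - 1)),
            0.10)
  # the mature-leaf plateau sits in the one-fifth to one-third band
  expect_gt(max(rr$rrna_ratio_mean), 1 / 5)
  expect_lt(max(rr$rrna_ratio_mean), 1 / 2)
})
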