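test_that("target assembly intersects dynamic and plastid-flagged genes", {
  ann <- tibble::tibble(
    gene_id = sprintf("g%d", 1:10),
    plastid_localized = c(rep(TRUE, 4), rep(FALSE, 6)))
  dyg <- sprintf("g%d", 1:10)
  expect_setequal(assemble_targets(dyg, ann, regulators = "g1"),
                  c("g2", "g3", "g4"))
  expect_setequal(assemble_targets(dyg, ann), sprintf("g%d", 1:4))
  none <- dplyr::mutate(ann, plastid_localized = FALSE)
  expect_error(assemble_targets(dyg, none),
               class = "ptj_error_empty_targets")
})

test_that("a regulator driving the target is ranked first among decoys", {
  set.seed(101)
  n_obs <- 45
  decoys <- matrix(rnorm(n_obs * 9), n_obs, 9,
                   dimnames = list(NULL, sprintf("decoy%d", 1:9)))
  driver <- rnorm(n_obs)
  target <- driver + rnorm(n_obs, sd = 0.2)
  m <- cbind(decoys, driver = driver, target = target)
  rk <- rank_regulators(m, targets = "target",
                        regulators = c(colnames(decoys), "driver"),
                        n_trees = 300, seed = 1)
  expect_equal(rk$ranks["target", "driver"], 1)
  expect_equal(unname(rowSums(rk$importance)), 1, tolerance = 1e-9)
})

test_that("constant targets are flagged as no-signal zero rows", {
  m <- cbind(matrix(rnorm(100), 50, 2,
                    dimnames = list(NULL, c("r1", "r2"))),
             flatline = rep(3, 50))
  rk <- rank_regulators(m, "flatline", c("r1", "r2"), n_trees = 50,
                        seed = 2)
  expect_true(rk$no_signal[["flatline"]])
  expect_equal(unname(rk$importance["flatline", ]), c(0, 0))
  expect_true(all(is.na(rk$ranks["flatline", ])))
})

test_that("regulator column order does not change the ranking", {
  set.seed(7)
  m <- matrix(rnorm(45 * 6), 45, 6,
              dimnames = list(NULL, c("t", sprintf("r%d", 1:5))))
  m[, "t"] <- m[, "r3"] + rnorm(45, sd = 0.3)
  regs <- sprintf("r%d", 1:5)
  rk1 <- rank_regulators(m, "t", regs, n_trees = 200, seed = 3)
  rk2 <- rank_regulators(m, "t", rev(regs), n_trees = 200, seed = 3)
  expect_equal(rk1$importance, rk2$importance)
})

test_that("deterministic under a fixed seed", {
  sim <- small_sim(seed = 17)
  gt <- sim$ground_truth
  obs <- network_observations(
    sim$expression, genes = c(gt$planted_edges$target,
                              gt$regulators$gene_id))
  run <- function() rank_regulators(obs, gt$planted_edges$target,
                                    gt$regulators$gene_id,
                                    n_trees = 100, seed = 5)
  expect_identical(run()$importance, run()$importance)
})

test_that("more trees never hurt planted-edge recovery", {
  recovery <- function(n_trees) {
    mean(sapply(1:5, function(s) {
      sim <- small_sim(seed = s)
      gt <- sim$ground_truth
      regs <- gt$regulators$gene_id
      obs <- network_observations(sim$expression,
                                  genes = c(gt$planted_edges$target, regs))
      rk <- rank_regulators(obs, gt$planted_edges$target, regs,
                            n_trees = n_trees, seed = s)
      top <- colnames(rk$importance)[apply(rk$importance, 1, which.max)]
      mean(top == paste0("REG_", gt$planted_edges$regulator))
    }))
  }
  expect_gte(recovery(500), recovery(100) - 0.05)
})

test_that("phase aggregation localises planted regulators to their phase", {
  sim <- small_sim(seed = 19)
  gt <- sim$ground_truth
  regs <- gt$regulators$gene_id
  obs <- network_observations(sim$expression,
                              genes = c(gt$planted_edges$target, regs))
  rk <- rank_regulators(obs, gt$planted_edges$target, regs,
                        n_trees = 200, seed = 4)
  modules <- gt$gene_modules[!is.na(gt$gene_modules$module), ]
  peaks <- gt$module_peak_samples
  # split so that planted targets fall on both sides: RCB/HEMERA/CIA2
  # drive modules peaking at samples 2-7, GLK1 the module peaking at 8
  phase_of_module <- setNames(
    ifelse(peaks <= 7, "plastid", "chloroplast"), seq_along(peaks))
  agg <- summarize_by_phase(rk, modules, phase_of_module)
  expect_setequal(unique(agg$phase), c("plastid", "chloroplast"))
  # REG_RCB drives plastid-phase targets (peak sample 6): its mean weight
  # there must exceed its weight among chloroplast-phase targets
  rcb <- tidyr::pivot_wider(
    agg[agg$regulator == "REG_RCB", c("phase", "mean_importance")],
    names_from = "phase", values_from = "mean_importance")
  expect_gt(rcb$plastid, rcb$chloroplast)
  # an unlabeled target raises an error
  expect_error(
    summarize_by_phase(rk, modules[0, ], phase_of_module),
    class = "ptj_error_unlabeled")
})
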