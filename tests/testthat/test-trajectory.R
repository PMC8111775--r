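test_that("summarize_cells reports order statistics per sample", {
  cells <- tibble::tibble(
    sample_id = rep(1:2, each = 48), replicate = rep(1:3, 32),
    cell_id = sprintf("c%d", 1:96),
    cell_area = c(rep(100, 48), 1:48),
    plastid_count = 10, mean_plastid_area = 2
  )
  s <- summarize_cells(cells)
  expect_equal(s$cell_area_median, c(100, 24.5))
  expect_equal(s$cell_area_q3 - s$cell_area_q1, c(0, 23.5))
  expect_equal(s$cell_area_min[2], 1)
  expect_equal(s$cell_area_max[2], 48)
  expect_equal(s$total_plastid_area_mean, c(20, 20))
  expect_error(summarize_cells(cells, expected_samples = 1:3),
               regexp = "sample 3 has no cells")
})

test_that("division rate corrects per-cell counts for cell division", {
  # two organelle rounds in 8 h with no cell division: fourfold, 6 rounds/day
  expect_equal(division_rate(8, 32, 1, 0, 1 / 3), 6)
  expect_equal(division_rate(10, 10, 1, 0, 1), 0)
  # cell division exactly offsets the halving of counts
  expect_equal(division_rate(10, 5, 2, 0, 1), 0)
  # invariance under uniform rescaling of counts
  expect_equal(division_rate(8, 32, 1.5, 1, 2),
               division_rate(80, 320, 1.5, 1, 2))
  expect_error(division_rate(0, 10, 1, 0, 1), class = "ptj_error_argument")
  expect_error(division_rate(8, 10, 1, 1, 1), class = "ptj_error_argument")
})

test_that("cumulative division rounds fall in the expected band", {
  expect_equal(cumulative_division_rounds(8, 72, 2), log2(18))
  expect_gt(cumulative_division_rounds(8, 72, 2), 4)
  expect_lt(cumulative_division_rounds(8, 72, 2), 5)
  expect_equal(cumulative_division_rounds(10, 10, 1), 0)
  # maintenance divisions: counts constant while cells double
  expect_equal(cumulative_division_rounds(10, 10, 2), 1)
})

test_that("growth rate mirrors division rate on total area", {
  expect_equal(growth_rate(50, 100, 1, 0, 1), 1)
  expect_equal(growth_rate(50, 50, 2, 0, 0.5), 2)
  expect_equal(growth_rate(50, 25, 2, 0, 3), 0)
})

test_that("chloroplast index is total plastid area over cell area", {
  expect_equal(chloroplast_index(100, 25, 5000), 0.5)
  expect_equal(chloroplast_index(1, 400, 400), 1)
  expect_error(chloroplast_index(0, 25, 5000),
               class = "ptj_error_argument")
})

test_that("phase detection finds the interior trough between the two humps", {
  g <- c(1.0, 3.0, 5.0, 3.6, 2.0, 1.2, 0.6, 0.3, 1.0, 2.2, 2.6, 1.3, 0.7)
  expect_equal(detect_phases(g)$transition, 8)
  expect_equal(detect_phases(g, smooth = FALSE)$transition, 8)
  # a small dip inside the first hump is absorbed by the smoothing
  wiggly <- c(4.8, 3.2, 5.0, 3.6, 2.0, 1.2, 0.6, 0.3, 1.0, 2.2, 2.6, 1.3,
              0.7)
  expect_equal(detect_phases(wiggly)$transition, 8)
  ph <- detect_phases(g)
  expect_equal(ph$plastid_phase, 1:7)
  expect_equal(ph$chloroplast_phase, 9:13)
  # monotone series has no biphasic structure
  expect_error(detect_phases(13:1), class = "ptj_error_no_biphasic")
  # equal minima: the earlier index wins
  tie <- c(5, 1, 5, 1, 5)
  expect_equal(detect_phases(tie, smooth = FALSE)$transition, 2)
  expect_error(detect_phases(c(1, 2, 3)), class = "ptj_error_argument")
})

test_that("trajectory rows satisfy the total-area identity A = N x a", {
  sim <- small_sim(seed = 3)
  traj <- organelle_trajectory(sim$cells, sim$cell_cycle, sim$sample_frame)
  s <- traj$samples
  expect_equal(s$total_plastid_area_mean,
               s$plastid_count_mean * s$mean_plastid_area_mean)
  expect_true(all(s$chloroplast_index >= 0))
  expect_length(traj$transition_sample, 1)
})

test_that("corrected rates recover the planted organelle proliferation", {
  sim <- small_sim(seed = 11)
  traj <- organelle_trajectory(sim$cells, sim$cell_cycle, sim$sample_frame)
  expect_equal(traj$cumulative_rounds,
               sim$ground_truth$organelle_rounds_total, tolerance = 0.3 / 4.5)
  # summed r_i x dt over the plastid-phase transitions telescopes to the same
  tr <- traj$transitions
  plastid <- which(tr$phase != "chloroplast")
  summed <- sum(tr$division_rate[plastid] *
                  (tr$age_to[plastid] - tr$age_from[plastid]))
  expect_equal(summed, sim$ground_truth$organelle_rounds_total,
               tolerance = 0.3 / 4.5)
})

test_that("division rate matches a brute-force lineage simulation", {
  for (case in list(list(p_org = 1, p_div = 0.6),
                    list(p_org = 0.5, p_div = 1),
                    list(p_org = 0, p_div = 0.3))) {
    lin <- simulate_lineage(n_cells = 1000, n0_mean = 40,
                            p_org = case$p_org, p_div = case$p_div,
                            seed = 99)
    r <- division_rate(lin$mean_before, lin$mean_after, lin$correction,
                       0, 1)
    # Monte-Carlo tolerance: ~1/sqrt(n_cells) on the mean count ratio
    expect_equal(r, lin$true_org_rounds, tolerance = 0.08)
  }
})
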