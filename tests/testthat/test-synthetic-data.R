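# The generator: determinism, planted structure, recorded truth.

test_that("simulated genomes are evenly spaced, split across chromosomes, deterministic", {
  cfg <- sim_config(seed = 1, n_genes = 4, n_chroms = 1, gene_spacing = 10000)
  g <- simulate_genome(cfg)
  expect_equal(length(unique(g$tss)), 4L)
  expect_true(all(diff(sort(g$tss)) >= 10000))
  expect_identical(simulate_genome(cfg), g)
  g2 <- simulate_genome(sim_config(seed = 1, n_genes = 10, n_chroms = 2))
  expect_equal(sort(unique(g2$chrom)), c("chr1", "chr2"))
  expect_equal(unname(table(g2$chrom)), c(5L, 5L), ignore_attr = TRUE)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(global_depletion = 0), "global_depletion")
  expect_error(sim_config(frac_down = 1.2), "fraction")
  expect_error(sim_config(frac_group2 = 0.7, frac_group3 = 0.5), "exceed")
})

test_that("no depletion and zero noise give identical WT and KO tracks", {
  cfg <- sim_config(seed = 2, n_genes = 100, n_chroms = 1,
                    global_depletion = 1, frac_group2 = 0, frac_group3 = 0,
                    signal_noise_sd = 0, depth_sd = 0)
  g <- simulate_genome(cfg)
  chip <- suppressMessages(simulate_chip(cfg, g))
  expect_equal(chip$tracks$H3K4me3$KO$values, chip$tracks$H3K4me3$WT$values)
  expect_equal(chip$truth$global_scale[["H3K4me3"]], 1)
})

test_that("disabling the broad tail removes extreme breadths", {
  cfg <- sim_config(seed = 3, n_genes = 800, n_chroms = 1,
                    broad_tail_fraction = 0)
  g <- simulate_genome(cfg)
  chip <- suppressMessages(simulate_chip(cfg, g, tracks = FALSE))
  b <- chip$truth$gene$me3_breadth
  # a single log-normal component: max / median stays far below the tail
  # that the default mixture produces (~21 kb vs ~1.5 kb median)
  expect_lt(max(b) / median(b), 5)
  cfg_tail <- sim_config(seed = 3, n_genes = 800, n_chroms = 1,
                         broad_tail_fraction = 0.1)
  chip_tail <- suppressMessages(simulate_chip(cfg_tail, g, tracks = FALSE))
  bt <- chip_tail$truth$gene$me3_breadth
  expect_gt(max(bt) / median(bt), 5)
})

test_that("the realised global scale tracks the configured depletion", {
  cfg <- sim_config(seed = 4, n_genes = 1000, n_chroms = 1,
                    global_depletion = 0.5, frac_group2 = 0, frac_group3 = 0)
  g <- simulate_genome(cfg)
  chip <- suppressMessages(simulate_chip(cfg, g))
  expect_equal(chip$truth$global_scale[["H3K4me3"]], 0.5, tolerance = 1e-6)
  # with group-ii/iii losses the realised scale drops below the factor
  cfg2 <- sim_config(seed = 4, n_genes = 1000, n_chroms = 1,
                     global_depletion = 0.5)
  chip2 <- suppressMessages(simulate_chip(cfg2, g))
  expect_lt(chip2$truth$global_scale[["H3K4me3"]], 0.5)
})

test_that("chip simulation is deterministic and peak output ignores the tracks flag", {
  cfg <- sim_config(seed = 5, n_genes = 150, n_chroms = 1)
  g <- simulate_genome(cfg)
  a <- suppressMessages(simulate_chip(cfg, g, tracks = FALSE))
  b <- suppressMessages(simulate_chip(cfg, g, tracks = TRUE))
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$truth$gene, b$truth$gene)
  c2 <- suppressMessages(simulate_chip(cfg, g, tracks = TRUE))
  expect_identical(b$tracks$H3K4me3$KO$values, c2$tracks$H3K4me3$KO$values)
  expect_identical(b$spike, c2$spike)
})

test_that("bulk truth tables reflect the planted fractions and coupling", {
  s <- quick_sim(seed = 6)
  bulk0 <- simulate_bulk_expression(
    sim_config(seed = 6, n_genes = 400, n_chroms = 1,
               frac_down = 0, frac_up = 0), s$genes, s$chip)
  expect_true(all(bulk0$truth$status == "stable"))

  cfg1 <- sim_config(seed = 6, n_genes = 400, n_chroms = 1,
                     extreme_coupling = 1)
  bulk1 <- simulate_bulk_expression(cfg1, s$genes, s$chip)
  downq <- bulk1$truth$quantile[bulk1$truth$status == "down"]
  expect_true(all(downq %in% c(1L, cfg1$q_quantiles)))
  expect_equal(sum(bulk1$truth$status == "down"),
               round(0.043 * 400))
})

test_that("planted log2 fold changes are recovered from the raw counts", {
  cfg <- sim_config(seed = 7, n_genes = 2000, n_chroms = 2,
                    lfc_mean = 1.5, lfc_sd = 0, de_min_mean = 20)
  g <- simulate_genome(cfg)
  chip <- suppressMessages(simulate_chip(cfg, g, tracks = FALSE))
  bulk <- simulate_bulk_expression(cfg, g, chip)
  down <- bulk$truth$status == "down"
  wt <- bulk$condition == "WT"
  obs <- log2(rowMeans(bulk$counts[down, !wt]) /
                rowMeans(bulk$counts[down, wt]))
  expect_equal(mean(obs), -1.5, tolerance = 0.2)
})

test_that("single-cell simulation is deterministic with planted dispersion inflation", {
  cfg <- sim_config(seed = 8, n_genes = 200, n_chroms = 1,
                    n_cells_per_cluster = 60, fano_inflation = 3,
                    fano_breadth_coupling = 0)
  g <- simulate_genome(cfg)
  a <- simulate_cells(cfg, g)
  b <- simulate_cells(cfg, g)
  expect_identical(a$cells$counts, b$cells$counts)
  expect_identical(a$cells$pseudotime, b$cells$pseudotime)
  f <- fano_by_cluster(a$cells)
  expect_gt(median(f$fano_2, na.rm = TRUE), median(f$fano_1, na.rm = TRUE))
  # cluster-1 pseudotime concentrated near zero, cluster 2 spread later
  pt1 <- a$cells$pseudotime[a$cells$cluster == "cluster1"]
  pt2 <- a$cells$pseudotime[a$cells$cluster == "cluster2"]
  expect_lt(median(pt1), 0.2)
  expect_gt(median(pt2), 0.4)
})
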