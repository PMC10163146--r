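# TSS classification, metagene profiles, fold changes and the DE stand-in.

test_that("group classification follows the >=1 bp TSS-window overlap rule", {
  genes <- make_genes(tss = 5000L)
  me3 <- make_peaks(5900L, 6100L)                 # window [4000, 6000): 100 bp
  me1 <- make_peaks(3999L, 4001L, mark = "H3K4me1")
  expect_equal(classify_tss_groups(genes, me3, me1)$group, "i")
  # no me3 overlap, 1 bp of me1 overlap -> group ii
  expect_equal(classify_tss_groups(genes, make_peaks(6000L, 6100L), me1)$group,
               "ii")
  # neither -> iii
  expect_equal(
    classify_tss_groups(genes, make_peaks(6000L, 6100L),
                        make_peaks(2000L, 3000L, mark = "H3K4me1"))$group,
    "iii")
})

test_that("classification matches the brute-force oracle on random toy genomes", {
  for (seed in 1:25) {
    toy <- random_toy(seed)
    got <- suppressWarnings(
      classify_tss_groups(toy$genes, toy$me3, toy$me1))
    expect_identical(got$group,
                     oracle_classify(toy$genes, toy$me3, toy$me1),
                     info = sprintf("toy seed %d", seed))
  }
})

test_that("classification is invariant to peak order and to splitting a peak", {
  genes <- make_genes(tss = c(5000L, 9000L, 30000L))
  me3 <- make_peaks(c(4500L, 8500L), c(5200L, 8800L))
  me1 <- make_peaks(29500L, 29800L, mark = "H3K4me1")
  base <- classify_tss_groups(genes, me3, me1)
  shuffled <- classify_tss_groups(genes, me3[2:1, ], me1)
  expect_equal(shuffled$group, base$group)
  # split the first peak into two abutting pieces
  split3 <- make_peaks(c(4500L, 4800L, 8500L), c(4800L, 5200L, 8800L))
  expect_equal(classify_tss_groups(genes, split3, me1)$group, base$group)
})

test_that("genes on chromosomes absent from peak calls fall in group iii with a warning", {
  genes <- make_genes(tss = 5000L, chrom = "chrZ")
  expect_warning(
    got <- classify_tss_groups(genes, make_peaks(4000L, 6000L),
                               make_peaks(1L, 10L, mark = "H3K4me1")),
    "absent")
  expect_equal(got$group, "iii")
})

test_that("planted group labels are recovered exactly from noise-free peaks", {
  cfg <- sim_config(seed = 3, n_genes = 300, n_chroms = 2,
                    frac_group2 = 0.2, frac_group3 = 0.05)
  genes <- simulate_genome(cfg)
  chip <- suppressMessages(simulate_chip(cfg, genes, tracks = FALSE))
  got <- classify_tss_groups(genes, chip$peaks$H3K4me3$KO,
                             chip$peaks$H3K4me1$KO)
  expect_identical(got$group, chip$truth$gene$group)
})

test_that("metagene profiles are constant on uniform signal and strand-oriented", {
  genes <- make_genes(tss = 5000L)
  uni <- make_track(chr1 = rep(3, 200))
  expect_equal(tss_metaprofile(uni, genes, flank = 2000, out_bin = 50),
               rep(3, 80))
  # signal only in the first bin downstream of a plus-strand TSS
  v <- numeric(400); v[5000 / 50 + 1] <- 7
  tr <- make_track(chr1 = v)
  plus <- tss_metaprofile(tr, genes, flank = 500, out_bin = 50)
  minus <- tss_metaprofile(tr, make_genes(tss = 5000L, strand = "-"),
                           flank = 500, out_bin = 50)
  expect_equal(which(plus > 0), 11L)   # right of centre (centre = 10|11 edge)
  expect_equal(minus, rev(plus))       # mirrored for the minus strand
  # averaging is linear over genes
  two <- make_genes(tss = c(5000L, 10000L))
  p1 <- tss_metaprofile(tr, two[1, ], flank = 500)
  p2 <- tss_metaprofile(tr, two[2, ], flank = 500)
  expect_equal(tss_metaprofile(tr, two, flank = 500), (p1 + p2) / 2)
})

test_that("windows beyond chromosome bounds are zero-padded and counted", {
  tr <- make_track(chr1 = rep(2, 40))
  prof <- tss_metaprofile(tr, make_genes(tss = 100L), flank = 500, out_bin = 50)
  expect_length(prof, 20L)
  expect_equal(prof[1:8], rep(0, 8))   # upstream of position 0
  expect_equal(prof[9:20], rep(2, 12))
})

test_that("binned fold change is 0 on identical tracks, ~1 on doubling, 0 on empty bins", {
  v <- c(rep(100, 200), rep(0, 200), rep(50, 200))
  a <- make_track(chr1 = v)
  expect_equal(binned_fold_change(a, a)$log2fc, rep(0, 3))
  b <- make_track(chr1 = 2 * v)
  fc <- binned_fold_change(a, b, pseudocount = 1)
  expect_equal(fc$log2fc[c(1, 3)], rep(1, 2), tolerance = 1e-3)
  expect_equal(fc$log2fc[2], 0)        # log2(pc/pc), never +/-Inf
  expect_error(binned_fold_change(a, make_track(chr9 = v)), "chromosomes")
})

test_that("TSS fold change matches hand-summed windows", {
  genes <- make_genes(tss = c(2000L, 6000L))
  va <- numeric(200); vb <- numeric(200)
  va[40:41] <- c(8, 8);  vb[40:41] <- c(2, 2)     # gene 1 window
  va[120:121] <- c(3, 5); vb[120:121] <- c(6, 10) # gene 2 window
  a <- make_track(chr1 = va); b <- make_track(chr1 = vb)
  fc <- tss_fold_change(a, b, genes, flank = 1000, pseudocount = 1)
  expect_equal(fc$log2fc, c(log2((4 + 1) / (16 + 1)), log2((16 + 1) / (8 + 1))))
  expect_equal(tss_fold_change(a, a, genes)$log2fc, c(0, 0))
  # quarter signal, far above the pseudocount -> about -2
  big <- make_track(chr1 = rep(4000, 200))
  quarter <- make_track(chr1 = rep(1000, 200))
  expect_equal(tss_fold_change(big, quarter, genes)$log2fc, rep(-2, 2),
               tolerance = 0.01)
})

test_that("group expression shift finds a planted group-iii deficit", {
  set.seed(42)
  assignment <- data.frame(
    gene_id = sprintf("g%03d", 1:120),
    group = rep(c("i", "ii", "iii"), times = c(80, 25, 15)))
  de <- data.frame(gene_id = assignment$gene_id,
                   log2fc = rnorm(120, 0, 0.3))
  de$log2fc[assignment$group == "iii"] <-
    de$log2fc[assignment$group == "iii"] - 2
  res <- group_expression_shift(de, assignment)
  expect_equal(res$summary$median[res$summary$group == "iii"], -2,
               tolerance = 0.35)
  iii_rows <- res$pairwise$group_a == "iii" | res$pairwise$group_b == "iii"
  expect_true(all(res$pairwise$padj[iii_rows] < 0.01))
})

test_that("degenerate groups are reported as missing, not p = 1", {
  de <- data.frame(gene_id = c("a", "b", "c"), log2fc = c(0, 1, 2))
  res <- group_expression_shift(
    de, data.frame(gene_id = c("a", "b", "c"), group = c("i", "i", "iii")))
  expect_true(is.na(res$pairwise$p))
  single <- group_expression_shift(
    de, data.frame(gene_id = c("a", "b", "c"), group = "i"))
  expect_null(single$pairwise)
  expect_equal(single$summary$n, 3L)
})

test_that("the DE stand-in applies the twofold threshold and zero-count rule", {
  set.seed(9)
  m <- matrix(rpois(5 * 6, 400), 5, 6,
              dimnames = list(paste0("g", 1:5), NULL))
  # gene 2: a clear but sub-twofold change stays stable regardless of p
  m[2, 4:6] <- rpois(3, 400 * 2^-0.5)
  m[5, ] <- 0
  de <- de_standin(m, rep(c("WT", "KO"), each = 3))
  expect_true(abs(de$log2fc[2]) < 1)
  expect_equal(de$status[2], "stable")
  expect_equal(de$status[5], "stable")
  expect_true(is.na(de$p[5]))
  expect_error(de_standin(m, c("WT", "WT", "WT", "KO", "KO", "XX")),
               "two condition levels")
})
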