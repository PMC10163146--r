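# Breadth quantiles, promoter assignment, enrichment and peak matching.

test_that("promoter assignment picks the max-overlap peak with stated tie rules", {
  genes <- make_genes(tss = 5000L)
  # overlaps of 300 bp vs 100 bp with the window [4000, 6000)
  pk <- make_peaks(c(5700L, 5900L), c(6300L, 6300L))
  got <- assign_promoter_peaks(pk, genes)
  expect_equal(got$peak_id, "p001")
  expect_equal(got$overlap, 300L)
  # equal overlap -> larger breadth wins
  pk2 <- make_peaks(c(5800L, 5500L), c(6200L, 6200L))
  expect_equal(assign_promoter_peaks(pk2, genes)$peak_id, "p002")
  # no overlap -> unassigned
  expect_equal(nrow(assign_promoter_peaks(make_peaks(8000L, 9000L), genes)), 0L)
})

test_that("promoter assignment matches the brute-force oracle on random toys", {
  for (seed in 26:50) {
    toy <- random_toy(seed)
    got <- assign_promoter_peaks(toy$me3, toy$genes)
    ora <- oracle_assign(toy$genes, toy$me3)
    got <- got[order(got$gene_id), ]; rownames(got) <- NULL
    ora <- ora[order(ora$gene_id), ]; rownames(ora) <- NULL
    expect_equal(got, ora, info = sprintf("toy seed %d", seed))
  }
})

test_that("breadth quantiles are equal-count, extremes ordered, deterministic under ties", {
  pk <- make_peaks(seq(0, 3900, by = 100), seq(0, 3900, by = 100) + 1:40)
  bq <- breadth_rank_quantiles(pk, Q = 20)
  expect_equal(unname(table(bq$assign$quantile)), rep(2L, 20),
               ignore_attr = TRUE)
  expect_equal(bq$assign$quantile[bq$assign$breadth == 1], 1L)
  expect_equal(bq$assign$quantile[bq$assign$breadth == 40], 20L)
  # all-equal breadths: order fixed by (chrom, start); reruns identical
  tie <- make_peaks(seq(0, 3900, by = 100), seq(0, 3900, by = 100) + 50)
  expect_identical(breadth_rank_quantiles(tie, 20)$assign,
                   breadth_rank_quantiles(tie, 20)$assign)
  # permutation invariance of the peak multiset
  perm <- breadth_rank_quantiles(pk[sample(40), ], Q = 20)
  expect_identical(perm$assign, bq$assign)
  expect_error(breadth_rank_quantiles(pk[1:10, ], Q = 20), "at least Q")
  # sizes differ by at most one when Q does not divide N
  bq7 <- breadth_rank_quantiles(pk, Q = 7)
  expect_lte(diff(range(table(bq7$assign$quantile))), 1L)
})

test_that("quantile enrichment reproduces the exhaustive hypergeometric tail", {
  # universe of 200 genes in 20 quantiles of 10; a 20-gene set with 5 hits
  # in one quantile
  genes_per_q <- split(sprintf("g%03d", 1:200), rep(1:20, each = 10))
  bq <- make_bq(genes_per_q)
  set <- c(genes_per_q[[10]][1:5], sprintf("g%03d", 185:199))
  enr <- quantile_set_enrichment(bq, set)
  manual <- sum(vapply(5:10, function(x) {
    choose(20, x) * choose(180, 10 - x) / choose(200, 10)
  }, numeric(1)))
  expect_equal(enr$p[enr$quantile == 10], manual, tolerance = 1e-12)
  expect_equal(sum(enr[1, c("a", "b", "c", "d")]), 200)
})

test_that("degenerate gene sets give p = 1 everywhere", {
  bq <- make_bq(split(sprintf("g%03d", 1:40), rep(1:4, each = 10)))
  expect_message(empty <- quantile_set_enrichment(bq, character(0)),
                 regexp = NA)
  expect_equal(empty$p, rep(1, 4))
  full <- quantile_set_enrichment(bq, sprintf("g%03d", 1:40))
  expect_equal(full$a, rep(10L, 4), ignore_attr = TRUE)
  expect_equal(full$p, rep(1, 4))
})

test_that("breadth-expression correlation handles monotone, tied and constant input", {
  bq <- make_bq(as.list(sprintf("g%03d", 1:10)))  # breadth increases with q
  b <- setNames(bq$assign$breadth, bq$gene_map$gene_id)
  expr_up <- setNames(as.numeric(rank(b)), names(b))
  expect_equal(breadth_expression_correlation(bq, expr_up)$rho, 1)
  # 5-point hand example with one tie: x = 1..5, y = (2, 1, 3, 3, 5)
  bq5 <- make_bq(as.list(sprintf("g%03d", 1:5)))
  y <- setNames(c(2, 1, 3, 3, 5), sprintf("g%03d", 1:5))
  hand_rho <- cor(rank(bq5$assign$breadth), rank(y))  # mid-ranked ties
  expect_equal(breadth_expression_correlation(bq5, y)$rho, hand_rho)
  const <- setNames(rep(2, 5), sprintf("g%03d", 1:5))
  expect_true(is.na(breadth_expression_correlation(bq5, const)$rho))
})

test_that("peak matching uses connected-component union spans", {
  a <- make_peaks(100L, 200L)
  b <- make_peaks(150L, 400L, condition = "KO", ids = "q001")
  m <- match_peaks_across_conditions(a, b)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$log2_change, log2(250 / 100))
  # disjoint -> one lost, one gained, no pair
  m2 <- match_peaks_across_conditions(make_peaks(0L, 100L),
                                      make_peaks(500L, 600L, ids = "q001"))
  expect_null(m2$pairs)
  expect_equal(m2$lost$peak_id, "p001")
  expect_equal(m2$gained$peak_id, "q001")
  # two a-peaks bridged by one b-peak form one component: spans 200 vs 100
  a3 <- make_peaks(c(0L, 120L), c(100L, 200L))
  b3 <- make_peaks(50L, 150L, ids = "q001")
  m3 <- match_peaks_across_conditions(a3, b3)
  expect_equal(nrow(m3$pairs), 1L)
  expect_equal(m3$pairs$log2_change, -1)
  # abutting peaks (zero shared bases) do NOT match
  m4 <- match_peaks_across_conditions(make_peaks(0L, 100L),
                                      make_peaks(100L, 200L, ids = "q001"))
  expect_null(m4$pairs)
})

test_that("peak matching is symmetric up to swapping lost/gained and sign", {
  set.seed(77)
  a <- make_peaks(s <- sort(sample.int(20000, 30)), s + sample.int(900, 30))
  b <- make_peaks(s2 <- sort(sample.int(20000, 25)), s2 + sample.int(900, 25),
                  ids = sprintf("q%03d", 1:25))
  ab <- match_peaks_across_conditions(a, b)
  ba <- match_peaks_across_conditions(b, a)
  expect_equal(sort(ab$lost$peak_id), sort(ba$gained$peak_id))
  expect_equal(sort(ab$gained$peak_id), sort(ba$lost$peak_id))
  expect_equal(sort(ab$pairs$log2_change), sort(-ba$pairs$log2_change))
})

test_that("breadth-change flagging respects the |log2| >= 1 boundary", {
  # component 1: 1024 -> 512 bp, log2 = -1 exactly  -> flagged
  # component 2: 1000 -> 505 bp, log2 = -0.986      -> unflagged
  a <- make_peaks(c(0L, 10000L), c(1024L, 11000L))
  b <- make_peaks(c(0L, 10000L), c(512L, 10505L), ids = c("q1", "q2"))
  m <- match_peaks_across_conditions(a, b)
  cls <- setNames(c("deep", "shallow"), c("p001", "p002"))
  res <- breadth_change_by_class(m, cls, flag_threshold = 1, n_rank_groups = 2)
  flagged <- setNames(res$summary$n_flagged, res$summary$class)
  expect_equal(unname(flagged["deep"]), 1L)
  expect_equal(unname(flagged["shallow"]), 0L)
})

test_that("zero breadth changes produce no flags and null enrichment p-values", {
  starts <- seq(0L, 90000L, by = 10000L)
  a <- make_peaks(starts, starts + 500L)
  b <- make_peaks(starts, starts + 500L, ids = sprintf("q%02d", 1:10))
  m <- match_peaks_across_conditions(a, b)
  cls <- setNames(rep(c("x", "y"), 5), a$peak_id)
  res <- breadth_change_by_class(m, cls, n_rank_groups = 2)
  expect_equal(sum(res$summary$n_flagged), 0L)
  expect_equal(res$flagged_enrichment$p, rep(1, 2))
  expect_equal(res$summary$median, c(0, 0))
})

test_that("a planted contraction of broad peaks is localised to the top rank groups", {
  set.seed(123)
  n <- 60
  starts <- seq(0L, by = 50000L, length.out = n)
  widths <- as.integer(c(rep(800, 40), rep(8000, 20)))  # broad top third
  a <- make_peaks(starts, starts + widths)
  width_b <- as.integer(ifelse(widths > 4000, widths %/% 2, widths))
  b <- make_peaks(starts, starts + width_b, ids = sprintf("q%03d", 1:n))
  m <- match_peaks_across_conditions(a, b)
  cls <- setNames(ifelse(widths > 4000, "broad", "typical"), a$peak_id)
  res <- breadth_change_by_class(m, cls, flag_threshold = 1, n_rank_groups = 3)
  med <- setNames(res$summary$median, res$summary$class)
  expect_equal(unname(med["broad"]), -1)
  expect_equal(unname(med["typical"]), 0)
  fe <- res$flagged_enrichment
  expect_lt(fe$p[fe$rank_group == 3], 1e-6)   # broad group holds all flags
  expect_equal(fe$a[fe$rank_group != 3], c(0L, 0L), ignore_attr = TRUE)
})
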