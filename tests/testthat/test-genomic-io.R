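# I/O boundary: coordinate conversion, sorted normal forms, round-trips.

test_that("GTF genes convert to 0-based half-open with strand-aware TSS", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    "# comment",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tgene_id \"gA\";",
    "chr1\tsrc\tgene\t101\t200\t.\t-\t.\tgene_id \"gB\";",
    "chr1\tsrc\texon\t101\t150\t.\t+\t.\tgene_id \"gA\";"), gtf)
  g <- read_gene_annotation(gtf, format = "gtf")
  expect_equal(nrow(g), 2L)
  expect_equal(g$start, c(100L, 100L))
  expect_equal(g$end, c(200L, 200L))
  expect_equal(g$tss, c(100L, 199L))
})

test_that("malformed GTF lines and duplicate ids are hard errors naming the line", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c("chr1\tsrc\tgene\t101\t200\t.\t+\t.\tgene_id \"gA\";",
               "chr1\tbroken line"), gtf)
  expect_error(read_gene_annotation(gtf, format = "gtf"), "line 2")
  writeLines(c("chr1\tsrc\tgene\t101\t200\t.\t+\t.\tgene_id \"gA\";",
               "chr1\tsrc\tgene\t501\t600\t.\t+\t.\tgene_id \"gA\";"), gtf)
  expect_error(read_gene_annotation(gtf, format = "gtf"), "duplicate")
})

test_that("TSV annotation round-trips unchanged", {
  genes <- make_genes(tss = c(500L, 1500L, 2500L), strand = c("+", "-", "+"))
  path <- tempfile(fileext = ".tsv")
  write_gene_annotation(genes, path)
  again <- read_gene_annotation(path, format = "tsv")
  expect_equal(again, genes)
  # second round-trip is byte-identical (idempotent)
  path2 <- tempfile(fileext = ".tsv")
  write_gene_annotation(again, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("minimal 4-column TSV annotation is accepted", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\ttss\tstrand", "gX\tchr1\t999\t-"), path)
  g <- read_gene_annotation(path, format = "tsv")
  expect_equal(g$tss, 999L)
  expect_equal(g$end, 1000L)
})

test_that("BED peaks: breadth, sorting, empty files, and invalid intervals", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr2\t10\t60", "chr1\t100\t250", "chr1\t5\t30"), bed)
  pk <- read_peaks(bed, mark = "H3K4me3", condition = "WT")
  expect_equal(pk$breadth, c(25L, 150L, 50L))  # sorted (chrom, start)
  expect_equal(pk$chrom, c("chr1", "chr1", "chr2"))
  expect_true(!is.unsorted(order(pk$chrom, pk$start)))

  file.create(empty <- tempfile(fileext = ".bed"))
  expect_equal(nrow(read_peaks(empty)), 0L)

  writeLines("chr1\t50\t50", bed)
  expect_error(read_peaks(bed), "start >= end")
})

test_that("write_peaks(read_peaks(x)) is a sorted normal form", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t500\t700\tb", "chr1\t100\t250\ta"), bed)
  pk <- read_peaks(bed)
  out <- tempfile(fileext = ".bed")
  write_peaks(pk, out)
  expect_identical(read_peaks(out)[c("chrom", "start", "end", "breadth")],
                   pk[c("chrom", "start", "end", "breadth")])
  out2 <- tempfile(fileext = ".bed")
  write_peaks(read_peaks(out), out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("bedGraph reading fills bins, zeroes gaps, conserves area", {
  bg <- tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t100\t2.0", "chr1\t200\t250\t4.0",
               "chr1\t250\t400\t0.5"), bg)
  tr <- read_signal(bg, bin_width = 50)
  expect_equal(tr$values$chr1, c(2, 2, 0, 0, 4, 0.5, 0.5, 0.5))
  # total area equals the hand-computed bedGraph area
  expect_equal(signal_area(tr), 2 * 100 + 4 * 50 + 0.5 * 150)
})

test_that("unaligned bedGraph intervals are rejected, not resampled", {
  bg <- tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t120\t1.0", bg)
  expect_error(read_signal(bg, bin_width = 50), "aligned")
})

test_that("signal write/read round-trips values and areas", {
  tr <- make_track(chr1 = c(0, 1.5, 1.5, 0, 3), chr2 = c(2, 2, 0.25))
  path <- tempfile(fileext = ".bedgraph")
  write_signal(tr, path)
  back <- read_signal(path, bin_width = 50,
                      chrom_lengths = c(chr1 = 250, chr2 = 150))
  expect_equal(back$values, tr$values)
  path2 <- tempfile(fileext = ".bedgraph")
  write_signal(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("counts, gene sets and single-cell matrices round-trip", {
  m <- matrix(rpois(12, 20), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  storage.mode(m) <- "double"
  p <- tempfile(fileext = ".tsv")
  write_counts(m, p, header = "# provenance")
  expect_equal(read_counts(p), m)

  sets <- list(alpha = c("g1", "g3"), beta = c("g2", "g4", "g1"))
  ps <- tempfile(fileext = ".gmt")
  write_gene_sets(sets, ps)
  expect_equal(read_gene_sets(ps), sets)

  counts <- matrix(rpois(60, 5) + 1L, 6, 10,
                   dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  cells <- cell_expression(counts, cluster = rep(c("c1", "c2"), each = 5),
                           pseudotime = seq(0, 1, length.out = 10))
  fm <- tempfile(fileext = ".mtx"); ff <- tempfile(); fme <- tempfile()
  write_cell_expression(cells, fm, ff, fme)
  back <- read_cell_expression(fm, ff, fme)
  expect_equal(unname(back$counts), unname(cells$counts))
  expect_equal(back$cluster, cells$cluster)
  expect_equal(back$pseudotime, cells$pseudotime)
})
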