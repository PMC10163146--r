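# In-code fixtures and independent oracles shared across the suite.

# -- tiny builders -----------------------------------------------------------

make_genes <- function(tss, chrom = "chr1", strand = "+", len = 200L) {
  n <- length(tss)
  chrom <- rep_len(chrom, n)
  strand <- rep_len(strand, n)
  start <- ifelse(strand == "+", tss, tss + 1L - len)
  end <- ifelse(strand == "+", tss + len, tss + 1L)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             strand = strand, tss = as.integer(tss), expressed = TRUE,
             stringsAsFactors = FALSE)
}

make_peaks <- function(start, end, chrom = "chr1", mark = "H3K4me3",
                       condition = "WT", ids = NULL) {
  n <- length(start)
  if (is.null(ids)) ids <- sprintf("p%03d", seq_len(n))
  data.frame(peak_id = ids, chrom = rep_len(chrom, n),
             start = as.integer(start), end = as.integer(end),
             breadth = as.integer(end - start),
             mark = mark, condition = condition, stringsAsFactors = FALSE)
}

make_track <- function(..., bin_width = 50) {
  signal_track(list(...), bin_width = bin_width)
}

# breadth_quantiles object with hand-chosen gene membership per quantile:
# `genes_per_q` is a list of character vectors; breadths are assigned so the
# stated quantile structure is exact.
make_bq <- function(genes_per_q) {
  Q <- length(genes_per_q)
  gene_ids <- unlist(genes_per_q, use.names = FALSE)
  peak_ids <- paste0("pk_", gene_ids)
  quantile <- rep(seq_len(Q), lengths(genes_per_q))
  assign <- data.frame(peak_id = peak_ids,
                       breadth = 100L * quantile + seq_along(peak_ids),
                       quantile = quantile, stringsAsFactors = FALSE)
  gene_map <- data.frame(gene_id = gene_ids, peak_id = peak_ids,
                         stringsAsFactors = FALSE)
  structure(list(assign = assign, Q = Q, gene_map = gene_map),
            class = "breadth_quantiles")
}

# -- independent oracles -----------------------------------------------------

# Exhaustive enumeration of the one-sided Fisher tail from first principles
# (binomial coefficients only; independent of phyper).
oracle_fisher_p <- function(a, b, c, d) {
  k <- a + b          # selection size
  m <- a + c          # successes in the urn
  n_tot <- a + b + c + d
  xs <- max(0, k - (n_tot - m)):min(k, m)
  mass <- choose(m, xs) * choose(n_tot - m, k - xs) / choose(n_tot, k)
  sum(mass[xs >= a])
}

# Brute-force all-pairs interval overlap in bp (0-based half-open).
oracle_overlap_bp <- function(ws, we, ps, pe) {
  pmax(0L, pmin(we, pe) - pmax(ws, ps))
}

# Brute-force group i/ii/iii classification over a toy genome.
oracle_classify <- function(genes, me3, me1, flank = 1000) {
  vapply(seq_len(nrow(genes)), function(g) {
    ws <- max(0L, genes$tss[g] - flank); we <- genes$tss[g] + flank
    hit <- function(pk) {
      same <- pk$chrom == genes$chrom[g]
      any(same & oracle_overlap_bp(ws, we, pk$start, pk$end) >= 1)
    }
    if (hit(me3)) "i" else if (hit(me1)) "ii" else "iii"
  }, character(1))
}

# Brute-force max-overlap promoter assignment under the stated tie rules.
oracle_assign <- function(genes, peaks, flank = 1000) {
  rows <- lapply(seq_len(nrow(genes)), function(g) {
    ws <- max(0L, genes$tss[g] - flank); we <- genes$tss[g] + flank
    same <- peaks$chrom == genes$chrom[g]
    ov <- ifelse(same, oracle_overlap_bp(ws, we, peaks$start, peaks$end), 0L)
    if (all(ov < 1)) return(NULL)
    cand <- which(ov >= 1)
    ord <- order(-ov[cand], -peaks$breadth[cand], peaks$start[cand],
                 peaks$peak_id[cand])
    best <- cand[ord[1]]
    data.frame(gene_id = genes$gene_id[g], peak_id = peaks$peak_id[best],
               overlap = ov[best], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(gene_id = character(), peak_id = character(),
                      overlap = integer()))
  do.call(rbind, rows)
}

# Random toy genome + peak set for the interval-logic oracle tests.
random_toy <- function(seed) {
  set.seed(seed)
  n_genes <- sample(3:100, 1)
  n_peaks <- sample(3:200, 1)
  chroms <- c("chrA", "chrB")
  genes <- make_genes(tss = sample.int(50000, n_genes),
                      chrom = sample(chroms, n_genes, replace = TRUE),
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      len = 100L)
  s <- sample.int(50000, n_peaks)
  w <- sample.int(3000, n_peaks)
  me3_n <- n_peaks %/% 2
  list(genes = genes,
       me3 = make_peaks(s[1:me3_n], s[1:me3_n] + w[1:me3_n],
                        chrom = sample(chroms, me3_n, replace = TRUE),
                        ids = sprintf("m3_%03d", 1:me3_n)),
       me1 = make_peaks(s[(me3_n + 1):n_peaks],
                        s[(me3_n + 1):n_peaks] + w[(me3_n + 1):n_peaks],
                        chrom = sample(chroms, n_peaks - me3_n, replace = TRUE),
                        mark = "H3K4me1",
                        ids = sprintf("m1_%03d", 1:(n_peaks - me3_n))))
}

# Shared small simulation used by several files (kept small for speed).
quick_sim <- function(seed = 1, ...) {
  cfg <- sim_config(seed = seed, n_genes = 400, n_chroms = 1, ...)
  genes <- simulate_genome(cfg)
  chip <- suppressMessages(simulate_chip(cfg, genes, tracks = FALSE))
  list(cfg = cfg, genes = genes, chip = chip)
}
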