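# Promoter chromatin-state operators: group i/ii/iii classification of TSSs
# by residual peak presence in the knockout, metagene TSS profiles, 10 kb
# genome-bin and TSS-window fold changes, per-group expression shifts, and
# a simple differential-expression stand-in with the study-style thresholds
# (twofold, adjusted p <= 0.01).

# All-pairs interval overlaps between a query and subject table of 0-based
# half-open intervals, per chromosome, via IRanges. Returns query index,
# subject index and overlap width (>= 1 bp).
interval_hits <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  out <- list()
  for (ch in unique(q_chrom)) {
    qi <- which(q_chrom == ch)
    si <- which(s_chrom == ch)
    if (length(si) == 0 || length(qi) == 0) next
    qr <- IRanges::IRanges(q_start[qi] + 1L, q_end[qi])
    sr <- IRanges::IRanges(s_start[si] + 1L, s_end[si])
    h <- IRanges::findOverlaps(qr, sr, minoverlap = 1L)
    if (length(h) == 0) next
    hf <- S4Vectors::queryHits(h)
    ht <- S4Vectors::subjectHits(h)
    ov <- IRanges::width(IRanges::pintersect(qr[hf], sr[ht]))
    out[[length(out) + 1L]] <- data.frame(
      query = qi[hf], subject = si[ht], overlap = ov)
  }
  if (length(out) == 0)
    return(data.frame(query = integer(), subject = integer(),
                      overlap = integer()))
  do.call(rbind, out)
}

# TSS windows [tss - flank, tss + flank), clipped at 0.
tss_windows <- function(genes, flank) {
  data.frame(chrom = genes$chrom,
             start = pmax(0L, genes$tss - as.integer(flank)),
             end = genes$tss + as.integer(flank))
}

#' Classify TSSs by residual methylation (groups i/ii/iii)
#'
#' Using knockout-condition peak calls: group `i` genes retain at least
#' some H3K4me3 at the TSS (>= 1 shared base between a H3K4me3 peak and
#' `TSS +/- flank`), group `ii` genes lost H3K4me3 but retain a H3K4me1
#' peak there, and group `iii` genes lost both. Groups are mutually
#' exclusive and exhaustive over the input genes.
#'
#' Genes on chromosomes absent from both peak files fall in group `iii`
#' with a warning.
#'
#' @param genes gene annotation `data.frame` (see
#'   [read_gene_annotation()]).
#' @param ko_me3_peaks,ko_me1_peaks peak tables for the knockout
#'   condition.
#' @param flank half-width of the TSS window in bp (default 1000, i.e.
#'   TSS +/- 1 kb).
#' @return `data.frame` with `gene_id`, `group` (`"i"`, `"ii"`, `"iii"`),
#'   and comma-separated supporting `me3_peaks` / `me1_peaks`.
#' @export
classify_tss_groups <- function(genes, ko_me3_peaks, ko_me1_peaks,
                                flank = 1000) {
  stopifnot(flank > 0)
  win <- tss_windows(genes, flank)
  peak_chroms <- unique(c(ko_me3_peaks$chrom, ko_me1_peaks$chrom))
  orphan <- !(genes$chrom %in% peak_chroms)
  if (any(orphan))
    warning(sprintf("%d gene(s) on chromosomes absent from peak files -> group iii",
                    sum(orphan)))
  collect <- function(peaks) {
    h <- interval_hits(win$chrom, win$start, win$end,
                       peaks$chrom, peaks$start, peaks$end)
    ids <- rep(NA_character_, nrow(genes))
    if (nrow(h) > 0) {
      sp <- split(peaks$peak_id[h$subject], h$query)
      ids[as.integer(names(sp))] <-
        vapply(sp, function(x) paste(sort(x), collapse = ","), character(1))
    }
    ids
  }
  me3 <- collect(ko_me3_peaks)
  me1 <- collect(ko_me1_peaks)
  group <- ifelse(!is.na(me3), "i", ifelse(!is.na(me1), "ii", "iii"))
  data.frame(gene_id = genes$gene_id, group = group,
             me3_peaks = me3, me1_peaks = me1, stringsAsFactors = FALSE)
}

# Mean signal of `track` over [start, end) in bp, snapping the window start
# to the track grid; positions beyond chromosome bounds contribute 0.
window_bins <- function(track, chrom, start, n_bins_out, ratio) {
  v <- track$values[[chrom]]
  if (is.null(v)) return(numeric(n_bins_out))
  bw <- track$bin_width
  i0 <- floor(start / bw)  # 0-based track-bin index of window start
  out <- numeric(n_bins_out)
  for (j in seq_len(n_bins_out)) {
    idx <- i0 + (j - 1L) * ratio + seq_len(ratio)  # 1-based into v
    idx_ok <- idx[idx >= 1 & idx <= length(v)]
    out[j] <- if (length(idx_ok) > 0) sum(v[idx_ok]) / ratio else 0
  }
  out
}

#' Average metagene profile around TSSs
#'
#' Per-gene windows `TSS +/- flank` are extracted from the binned signal
#' track, oriented 5' to 3' (minus-strand windows reversed) and averaged.
#' Windows exceeding chromosome bounds are zero-padded and still counted.
#' Window starts are snapped to the track grid.
#'
#' @param track a `signal_track`.
#' @param genes gene annotation `data.frame` (must be non-empty).
#' @param flank half-width in bp; must be a multiple of `out_bin`.
#' @param out_bin output bin width; the track `bin_width` must divide it.
#' @return numeric vector of length `2 * flank / out_bin`: the mean signal
#'   profile, upstream to downstream.
#' @export
tss_metaprofile <- function(track, genes, flank = 2000, out_bin = 50) {
  if (nrow(genes) == 0) stop_("empty gene list")
  if (flank %% out_bin != 0) stop_("flank must be a multiple of out_bin")
  if (out_bin %% track$bin_width != 0)
    stop_("track bin_width (%d) must divide out_bin (%d)",
          track$bin_width, out_bin)
  ratio <- out_bin %/% track$bin_width
  n_out <- 2L * flank %/% out_bin
  acc <- numeric(n_out)
  for (g in seq_len(nrow(genes))) {
    prof <- window_bins(track, genes$chrom[g], genes$tss[g] - flank,
                        n_out, ratio)
    if (genes$strand[g] == "-") prof <- rev(prof)
    acc <- acc + prof
  }
  acc / nrow(genes)
}

# Re-bin a track's per-chromosome vectors into coarser bins by summation.
rebin_sums <- function(track, bin_size) {
  if (bin_size %% track$bin_width != 0)
    stop_("bin_size must be a multiple of track bin_width")
  r <- bin_size %/% track$bin_width
  lapply(track$values, function(v) {
    n_out <- ceiling(length(v) / r)
    pad <- n_out * r - length(v)
    if (pad > 0) v <- c(v, numeric(pad))
    colSums(matrix(v, nrow = r))
  })
}

#' Genome-bin log2 fold change between two tracks
#'
#' Signal is summed into `bin_size` bins tiling each chromosome and the
#' per-bin change is `log2((sum_b + pc) / (sum_a + pc))`; the pseudocount
#' keeps empty bins at exactly 0 rather than +/-Inf.
#'
#' @param track_a,track_b `signal_track`s sharing `bin_width` and
#'   chromosomes (a = reference, b = comparison, i.e. KO vs WT is
#'   `track_a = WT`).
#' @param bin_size output bin size in bp (default 10 kb).
#' @param pseudocount positive signal pseudocount per bin.
#' @return `data.frame` with `chrom`, `bin_start`, `bin_end`,
#'   `enrichment_a`, `enrichment_b`, `log2fc`.
#' @export
binned_fold_change <- function(track_a, track_b, bin_size = 10000,
                               pseudocount = 1) {
  stopifnot(pseudocount > 0)
  if (track_a$bin_width != track_b$bin_width)
    stop_("tracks have different bin_width")
  if (!setequal(names(track_a$values), names(track_b$values)))
    stop_("tracks cover different chromosomes")
  sa <- rebin_sums(track_a, bin_size)
  sb <- rebin_sums(track_b, bin_size)
  out <- lapply(names(sa), function(ch) {
    a <- sa[[ch]]; b <- sb[[ch]]
    n <- max(length(a), length(b))
    length(a) <- n; length(b) <- n
    a[is.na(a)] <- 0; b[is.na(b)] <- 0
    chrom_len_a <- length(track_a$values[[ch]]) * track_a$bin_width
    chrom_len_b <- length(track_b$values[[ch]]) * track_b$bin_width
    ends <- pmin(seq_len(n) * bin_size, max(chrom_len_a, chrom_len_b))
    data.frame(chrom = ch, bin_start = (seq_len(n) - 1L) * bin_size,
               bin_end = ends, enrichment_a = a, enrichment_b = b,
               log2fc = log2((b + pseudocount) / (a + pseudocount)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' TSS-window log2 fold change between two tracks
#'
#' Signal is summed over `TSS +/- flank` for every gene (window snapped to
#' the track grid) and the change is
#' `log2((sum_b + pc) / (sum_a + pc))`. Applies identically to any mark's
#' tracks (H3K4me3/me1, H3K27ac, H3K27me3).
#'
#' @inheritParams binned_fold_change
#' @param genes gene annotation `data.frame`.
#' @param flank half-width of the TSS window in bp (default 1 kb).
#' @return `data.frame` with `gene_id`, `sum_a`, `sum_b`, `log2fc`.
#' @export
tss_fold_change <- function(track_a, track_b, genes, flank = 1000,
                            pseudocount = 1) {
  stopifnot(pseudocount > 0, flank > 0)
  if (track_a$bin_width != track_b$bin_width)
    stop_("tracks have different bin_width")
  bw <- track_a$bin_width
  n_bins <- ceiling(2 * flank / bw)
  sum_win <- function(track, g) {
    sum(window_bins(track, genes$chrom[g], genes$tss[g] - flank,
                    n_bins, 1L))
  }
  sa <- vapply(seq_len(nrow(genes)), function(g) sum_win(track_a, g),
               numeric(1))
  sb <- vapply(seq_len(nrow(genes)), function(g) sum_win(track_b, g),
               numeric(1))
  data.frame(gene_id = genes$gene_id, sum_a = sa, sum_b = sb,
             log2fc = log2((sb + pseudocount) / (sa + pseudocount)),
             stringsAsFactors = FALSE)
}

#' Expression shift by chromatin-state group
#'
#' Summarises per-group distributions of expression log2 fold change and
#' compares every group pair with Wilcoxon rank-sum tests, BH-corrected.
#' Pairs involving a group with fewer than two genes are reported with
#' missing p-values rather than 1.
#'
#' @param de DE table (`gene_id`, `log2fc`, ...), covering every gene in
#'   `assignment`.
#' @param assignment output of [classify_tss_groups()] (or any
#'   `gene_id`/`group` table).
#' @return list with `summary` (per-group n/median/quartiles) and
#'   `pairwise` (`group_a`, `group_b`, `p`, `padj`).
#' @export
group_expression_shift <- function(de, assignment) {
  miss <- setdiff(assignment$gene_id, de$gene_id)
  if (length(miss) > 0)
    stop_("%d gene(s) in assignment missing from DE table", length(miss))
  lfc <- setNames(de$log2fc, de$gene_id)[assignment$gene_id]
  groups <- split(lfc, assignment$group)
  summary <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    data.frame(group = g, n = length(x), median = median(x),
               q1 = unname(quantile(x, 0.25)), q3 = unname(quantile(x, 0.75)),
               stringsAsFactors = FALSE)
  }))
  pairwise <- NULL
  gn <- names(groups)
  if (length(gn) >= 2) {
    combs <- utils::combn(gn, 2)
    p <- apply(combs, 2, function(pr) {
      x <- groups[[pr[1]]]; y <- groups[[pr[2]]]
      if (length(x) < 2 || length(y) < 2) return(NA_real_)
      suppressWarnings(wilcox.test(x, y)$p.value)
    })
    pairwise <- data.frame(group_a = combs[1, ], group_b = combs[2, ],
                           p = p, padj = bh_adjust(p),
                           stringsAsFactors = FALSE)
  }
  list(summary = summary, pairwise = pairwise)
}

#' Differential-expression stand-in (t-test on log-scale values)
#'
#' A deliberately simple two-condition DE caller used as pipeline
#' plumbing: per-gene log2 fold change of (optionally spike-normalised)
#' mean expression with a pseudocount, a two-sample t-test on
#' `log2(norm + pc)` values, BH adjustment, and the twofold /
#' adjusted-p <= 0.01 status rule: `down`/`up` iff
#' `|log2FC| >= lfc_threshold` and `padj <= alpha`, else `stable`. Users
#' with a dedicated DE engine can supply its table anywhere a `DETable`
#' is consumed.
#'
#' By default the pooled-variance test is used: with the typical two to
#' three replicates per condition, the Welch-Satterthwaite degrees of
#' freedom routinely collapse towards 2, which caps attainable p-values
#' near `1e-3` and leaves the caller with essentially no power after BH
#' correction regardless of effect size. The pooled test keeps the full
#' `n1 + n2 - 2` degrees of freedom (group variances are exchangeable
#' under this design); set `pool_variance = FALSE` for Welch's test when
#' replicate numbers are larger.
#'
#' Genes with zero counts in every sample are `stable` with missing p.
#'
#' @param counts genes x samples matrix of raw counts.
#' @param condition_labels vector of length `ncol(counts)` with exactly
#'   two levels; the first level (factor order, or order of appearance)
#'   is the reference, and `log2fc` is second vs first.
#' @param lfc_threshold absolute log2 fold-change cutoff (default 1,
#'   i.e. twofold).
#' @param alpha adjusted-p cutoff (default 0.01).
#' @param spike_counts optional per-sample spike reads for
#'   [normalized_expression()]; `NULL` uses raw counts.
#' @param pseudocount added before taking logs.
#' @param pool_variance use the pooled-variance t-test (default); `FALSE`
#'   gives Welch's unequal-variance test.
#' @return `data.frame` (a `DETable`) with `gene_id`, `log2fc`, `p`,
#'   `padj`, `status`.
#' @export
de_standin <- function(counts, condition_labels, lfc_threshold = 1,
                       alpha = 0.01, spike_counts = NULL, pseudocount = 1,
                       pool_variance = TRUE) {
  stopifnot(is.matrix(counts))
  labs <- if (is.factor(condition_labels)) condition_labels
          else factor(condition_labels, levels = unique(condition_labels))
  if (nlevels(labs) != 2) stop_("need exactly two condition levels")
  if (any(table(labs) < 2)) stop_("need >= 2 samples per condition")
  norm <- if (is.null(spike_counts)) counts
          else normalized_expression(counts, spike_counts)
  lx <- log2(norm + pseudocount)
  ref <- lx[, labs == levels(labs)[1], drop = FALSE]
  alt <- lx[, labs == levels(labs)[2], drop = FALSE]
  lfc <- rowMeans(alt) - rowMeans(ref)
  allzero <- rowSums(counts) == 0
  p <- rep(NA_real_, nrow(counts))
  for (g in which(!allzero)) {
    p[g] <- tryCatch(t.test(alt[g, ], ref[g, ], var.equal = pool_variance)$p.value,
                     error = function(e) if (lfc[g] == 0) NA_real_ else 0)
  }
  lfc[allzero] <- 0
  padj <- bh_adjust(p)
  status <- rep("stable", nrow(counts))
  sig <- !is.na(padj) & padj <= alpha & abs(lfc) >= lfc_threshold
  status[sig & lfc < 0] <- "down"
  status[sig & lfc > 0] <- "up"
  data.frame(gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             log2fc = lfc, p = p, padj = padj, status = status,
             stringsAsFactors = FALSE)
}
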