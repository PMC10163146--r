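# Peak-breadth stratification: promoter-peak assignment, ranking peaks
# into equal-count breadth quantiles (narrowest = 1), quantile-wise
# one-sided Fisher gene-set enrichment, breadth-expression correlation,
# cross-condition peak matching by connected-component union spans, and
# breadth-change statistics by gene class.

#' Assign promoter peaks to genes
#'
#' A gene's promoter peak is the peak overlapping `TSS +/- flank` with the
#' largest overlap; ties are broken by larger breadth, then leftmost
#' start, then peak id. Genes without any overlapping peak are unassigned
#' (absent from the result); one peak may serve several genes.
#'
#' @param peaks peak table for a single mark/condition.
#' @param genes gene annotation `data.frame`.
#' @param flank half-width of the TSS window in bp (default 1 kb).
#' @return `data.frame` with `gene_id`, `peak_id`, `overlap` (bp).
#' @export
assign_promoter_peaks <- function(peaks, genes, flank = 1000) {
  win <- tss_windows(genes, flank)
  h <- interval_hits(win$chrom, win$start, win$end,
                     peaks$chrom, peaks$start, peaks$end)
  if (nrow(h) == 0)
    return(data.frame(gene_id = character(), peak_id = character(),
                      overlap = integer(), stringsAsFactors = FALSE))
  h$breadth <- peaks$breadth[h$subject]
  h$pstart <- peaks$start[h$subject]
  h$pid <- peaks$peak_id[h$subject]
  # best peak per gene under the stated tie rules
  ord <- order(h$query, -h$overlap, -h$breadth, h$pstart, h$pid)
  h <- h[ord, , drop = FALSE]
  best <- h[!duplicated(h$query), , drop = FALSE]
  data.frame(gene_id = genes$gene_id[best$query], peak_id = best$pid,
             overlap = best$overlap, stringsAsFactors = FALSE)
}

#' Rank peaks into equal-count breadth quantiles
#'
#' Peaks are stably sorted by `(breadth, chrom, start)` and cut into `Q`
#' consecutive blocks whose sizes differ by at most one (the first
#' `N mod Q` quantiles take the extra peak). Quantile 1 holds the
#' narrowest peaks, quantile `Q` the broadest. The assignment is a
#' deterministic, permutation-invariant function of the peak multiset.
#'
#' @param peaks peak table (single mark/condition); needs `>= Q` rows.
#' @param Q number of quantiles (default 20, i.e. 5% of peaks each).
#' @param gene_map optional promoter assignment from
#'   [assign_promoter_peaks()], carried along for gene-level operations.
#' @return object of class `breadth_quantiles`: list with `assign`
#'   (`peak_id`, `breadth`, `quantile`), `Q`, `gene_map`.
#' @export
breadth_rank_quantiles <- function(peaks, Q = 20, gene_map = NULL) {
  n <- nrow(peaks)
  if (n < Q) stop_("need at least Q=%d peaks, have %d", Q, n)
  ord <- order(peaks$breadth, peaks$chrom, peaks$start, peaks$peak_id)
  base <- n %/% Q
  extra <- n %% Q
  sizes <- rep(base, Q) + c(rep(1L, extra), rep(0L, Q - extra))
  q <- rep(seq_len(Q), times = sizes)
  assign <- data.frame(peak_id = peaks$peak_id[ord],
                       breadth = peaks$breadth[ord],
                       quantile = q, stringsAsFactors = FALSE)
  structure(list(assign = assign, Q = Q, gene_map = gene_map),
            class = "breadth_quantiles")
}

#' @export
print.breadth_quantiles <- function(x, ...) {
  cat(sprintf("breadth quantiles: %d peaks in Q=%d quantiles (%s genes mapped)\n",
              nrow(x$assign), x$Q,
              if (is.null(x$gene_map)) "no" else nrow(x$gene_map)))
  invisible(x)
}

# Per-gene quantile lookup for a breadth_quantiles object with a gene map.
gene_quantiles <- function(bq) {
  if (is.null(bq$gene_map))
    stop_("breadth_quantiles has no gene_map; run assign_promoter_peaks first")
  q <- setNames(bq$assign$quantile, bq$assign$peak_id)
  data.frame(gene_id = bq$gene_map$gene_id,
             quantile = unname(q[bq$gene_map$peak_id]),
             stringsAsFactors = FALSE)
}

#' Quantile-wise gene-set enrichment (one-sided Fisher)
#'
#' For each breadth quantile, tests whether the gene set is
#' over-represented among genes whose promoter peak falls in that
#' quantile, using the upper hypergeometric tail (enrichment only;
#' depletion shows as p near 1). BH adjustment is applied across the `Q`
#' tests.
#'
#' @param bq a `breadth_quantiles` object with a gene map.
#' @param gene_set character vector of gene ids; genes outside the
#'   universe are dropped with a message.
#' @param universe optional character vector; defaults to all genes with
#'   an assigned promoter peak.
#' @return `data.frame` with one row per quantile: `quantile`, `a`, `b`,
#'   `c`, `d`, `odds_ratio`, `p`, `padj`.
#' @export
quantile_set_enrichment <- function(bq, gene_set, universe = NULL) {
  gq <- gene_quantiles(bq)
  if (!is.null(universe)) gq <- gq[gq$gene_id %in% universe, , drop = FALSE]
  if (nrow(gq) == 0) stop_("empty universe")
  dropped <- length(setdiff(gene_set, gq$gene_id))
  if (dropped > 0)
    message(sprintf("quantile_set_enrichment: %d set gene(s) outside universe dropped",
                    dropped))
  set <- intersect(gene_set, gq$gene_id)
  n_univ <- nrow(gq)
  n_set <- length(set)
  rows <- lapply(seq_len(bq$Q), function(q) {
    in_q <- gq$gene_id[gq$quantile == q]
    a <- length(intersect(set, in_q))
    b <- length(in_q) - a
    cc <- n_set - a
    d <- n_univ - a - b - cc
    ft <- fisher_one_sided(a, b, cc, d)
    data.frame(quantile = q, a = a, b = b, c = cc, d = d,
               odds_ratio = ft$odds_ratio, p = ft$p)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out
}

#' Correlation between promoter peak breadth and expression
#'
#' Spearman's rank correlation (ties mid-ranked) between per-gene
#' promoter-peak breadth and mean normalised expression, reported as the
#' headline statistic, with Pearson's r alongside. Genes present in both
#' inputs are used.
#'
#' @param bq a `breadth_quantiles` object with a gene map.
#' @param expression named numeric vector of per-gene expression.
#' @return list with `rho`, `p`, `pearson_r`, `pearson_p`, `n`. `rho` is
#'   `NA` when either vector is constant.
#' @export
breadth_expression_correlation <- function(bq, expression) {
  gq <- gene_quantiles(bq)
  bmap <- setNames(bq$assign$breadth, bq$assign$peak_id)
  breadth <- setNames(unname(bmap[bq$gene_map$peak_id]), bq$gene_map$gene_id)
  common <- intersect(names(breadth), names(expression))
  if (length(common) < 3) stop_("need >= 3 genes with both values")
  x <- breadth[common]
  y <- expression[common]
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, pearson_r = NA_real_,
                pearson_p = NA_real_, n = length(common)))
  sp <- suppressWarnings(cor.test(x, y, method = "spearman"))
  pe <- cor.test(x, y, method = "pearson")
  list(rho = unname(sp$estimate), p = sp$p.value,
       pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       n = length(common))
}

#' Match peaks across two conditions
#'
#' Builds the overlap graph (>= 1 shared base) over the combined peak set
#' and treats each connected component as one matched unit: the union
#' span of each side (leftmost start to rightmost end of that side's
#' peaks) is compared, giving
#' `log2(span_b / span_a)` per matched component. Components with peaks
#' on only one side are reported as lost (a-only) or gained (b-only).
#' This rule is robust to peaks splitting or merging between conditions.
#'
#' @param peaks_a,peaks_b peak tables for the same mark in two
#'   conditions.
#' @return object of class `peak_match`: list with `pairs`
#'   (`component`, `chrom`, representative `peak_a`/`peak_b` ids,
#'   `n_a`, `n_b`, `span_a`, `span_b`, `overlap`, `log2_change`),
#'   `lost`, `gained` (peak tables).
#' @export
match_peaks_across_conditions <- function(peaks_a, peaks_b) {
  all_pk <- rbind(
    data.frame(chrom = peaks_a$chrom, start = peaks_a$start,
               end = peaks_a$end, peak_id = peaks_a$peak_id, side = "a",
               stringsAsFactors = FALSE),
    data.frame(chrom = peaks_b$chrom, start = peaks_b$start,
               end = peaks_b$end, peak_id = peaks_b$peak_id, side = "b",
               stringsAsFactors = FALSE))
  if (nrow(all_pk) == 0)
    return(structure(list(pairs = NULL, lost = peaks_a, gained = peaks_b),
                     class = "peak_match"))
  all_pk$component <- NA_integer_
  comp_rows <- list()
  next_comp <- 0L
  for (ch in unique(all_pk$chrom)) {
    idx <- which(all_pk$chrom == ch)
    ir <- IRanges::IRanges(all_pk$start[idx] + 1L, all_pk$end[idx])
    # min.gapwidth = 0: merge strictly overlapping ranges only (>= 1 bp),
    # never merely abutting ones
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    ov <- IRanges::findOverlaps(ir, red, minoverlap = 1L)
    comp_local <- integer(length(idx))
    comp_local[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
    all_pk$component[idx] <- next_comp + comp_local
    next_comp <- next_comp + length(red)
  }
  pairs <- list(); lost <- character(); gained <- character()
  for (cmp in split(seq_len(nrow(all_pk)), all_pk$component)) {
    sub <- all_pk[cmp, , drop = FALSE]
    a_rows <- sub[sub$side == "a", , drop = FALSE]
    b_rows <- sub[sub$side == "b", , drop = FALSE]
    if (nrow(a_rows) == 0) {
      gained <- c(gained, b_rows$peak_id)
    } else if (nrow(b_rows) == 0) {
      lost <- c(lost, a_rows$peak_id)
    } else {
      span_a <- max(a_rows$end) - min(a_rows$start)
      span_b <- max(b_rows$end) - min(b_rows$start)
      ov_bp <- max(0L, min(max(a_rows$end), max(b_rows$end)) -
                     max(min(a_rows$start), min(b_rows$start)))
      pairs[[length(pairs) + 1L]] <- data.frame(
        component = sub$component[1], chrom = sub$chrom[1],
        peak_a = paste(sort(a_rows$peak_id), collapse = ","),
        peak_b = paste(sort(b_rows$peak_id), collapse = ","),
        n_a = nrow(a_rows), n_b = nrow(b_rows),
        span_a = span_a, span_b = span_b, overlap = ov_bp,
        log2_change = log2(span_b / span_a), stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else NULL
  structure(list(pairs = pairs,
                 lost = peaks_a[peaks_a$peak_id %in% lost, , drop = FALSE],
                 gained = peaks_b[peaks_b$peak_id %in% gained, , drop = FALSE]),
            class = "peak_match")
}

#' @export
print.peak_match <- function(x, ...) {
  cat(sprintf("peak match: %d matched component(s), %d lost, %d gained\n",
              if (is.null(x$pairs)) 0L else nrow(x$pairs),
              nrow(x$lost), nrow(x$gained)))
  invisible(x)
}

#' Breadth change by gene/peak class
#'
#' Summarises the log2 breadth change of matched peaks per class (for
#' example down / stable / up genes), runs pairwise Wilcoxon rank-sum
#' tests with BH correction between classes, flags "significantly
#' changed" components (`|log2 change| >= flag_threshold`), and tests the
#' enrichment of flagged components across breadth-rank groups of the
#' reference condition with one-sided Fisher tests.
#'
#' @param match a `peak_match` from [match_peaks_across_conditions()].
#' @param classes named character vector mapping reference-condition
#'   (`a`-side) peak ids to class labels; components whose a-side peaks
#'   carry conflicting labels are dropped with a warning, unlabelled
#'   components are ignored.
#' @param flag_threshold absolute log2 breadth-change flag cutoff
#'   (default 1; a change of exactly the threshold is flagged).
#' @param n_rank_groups number of equal-count breadth-rank groups of the
#'   a-side span used for the flagged-peak enrichment (default 5).
#' @return list with `summary` (per-class n/median/quartiles/n_flagged),
#'   `pairwise` (Wilcoxon BH table), `flagged_enrichment` (per rank
#'   group: counts, odds ratio, one-sided p, padj), `flag_threshold`.
#' @export
breadth_change_by_class <- function(match, classes, flag_threshold = 1,
                                    n_rank_groups = 5) {
  pairs <- match$pairs
  if (is.null(pairs) || nrow(pairs) == 0) stop_("no matched peak pairs")
  cls <- vapply(seq_len(nrow(pairs)), function(i) {
    ids <- strsplit(pairs$peak_a[i], ",", fixed = TRUE)[[1]]
    lab <- unique(classes[ids])
    lab <- lab[!is.na(lab)]
    if (length(lab) == 1) lab else if (length(lab) == 0) NA_character_
    else "conflict"
  }, character(1))
  if (any(cls == "conflict", na.rm = TRUE)) {
    warning(sprintf("%d component(s) with conflicting class labels dropped",
                    sum(cls == "conflict", na.rm = TRUE)))
    cls[cls == "conflict"] <- NA_character_
  }
  pairs$class <- cls
  pairs$flagged <- abs(pairs$log2_change) >= flag_threshold
  lab_pairs <- pairs[!is.na(pairs$class), , drop = FALSE]
  groups <- split(lab_pairs$log2_change, lab_pairs$class)
  empty <- names(groups)[vapply(groups, length, integer(1)) == 0]
  if (length(empty) > 0) warning("empty class(es) skipped: ",
                                 paste(empty, collapse = ", "))
  summary <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    data.frame(class = g, n = length(x), median = median(x),
               q1 = unname(quantile(x, 0.25)), q3 = unname(quantile(x, 0.75)),
               n_flagged = sum(lab_pairs$flagged[lab_pairs$class == g]),
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
    pairwise <- data.frame(class_a = combs[1, ], class_b = combs[2, ],
                           p = p, padj = bh_adjust(p),
                           stringsAsFactors = FALSE)
  }
  # enrichment of flagged components across breadth-rank groups of span_a
  fe <- NULL
  if (nrow(pairs) >= n_rank_groups) {
    ord <- order(pairs$span_a, pairs$chrom, pairs$component)
    base <- nrow(pairs) %/% n_rank_groups
    extra <- nrow(pairs) %% n_rank_groups
    sizes <- rep(base, n_rank_groups) +
      c(rep(1L, extra), rep(0L, n_rank_groups - extra))
    rg <- integer(nrow(pairs))
    rg[ord] <- rep(seq_len(n_rank_groups), times = sizes)
    n_flag <- sum(pairs$flagged)
    fe <- do.call(rbind, lapply(seq_len(n_rank_groups), function(g) {
      a <- sum(pairs$flagged & rg == g)
      b <- sum(rg == g) - a
      cc <- n_flag - a
      d <- nrow(pairs) - a - b - cc
      ft <- fisher_one_sided(a, b, cc, d)
      data.frame(rank_group = g, a = a, b = b, c = cc, d = d,
                 odds_ratio = ft$odds_ratio, p = ft$p)
    }))
    fe$padj <- bh_adjust(fe$p)
  }
  list(summary = summary, pairwise = pairwise, flagged_enrichment = fe,
       flag_threshold = flag_threshold)
}
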