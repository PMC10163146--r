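# Shared statistical machinery: one-sided Fisher/hypergeometric tail,
# Benjamini-Hochberg adjustment, unweighted GSEA-style running enrichment
# with a gene-set permutation null, and the stratified rank-rank
# hypergeometric overlap map.

#' One-sided Fisher's exact test (enrichment tail)
#'
#' For the 2x2 table `(a, b; c, d)` (`a` = in-set and in-selection),
#' returns the upper hypergeometric tail `P(X >= a)` with the table's
#' margins, i.e. the one-sided enrichment p-value, together with the
#' sample odds ratio `ad/bc`.
#'
#' Degenerate margins give `p = 1`; a `0/0` odds ratio is `NA`.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return list with elements `p` and `odds_ratio`.
#' @export
fisher_one_sided <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_("cell counts must be non-negative integers")
  # margins: selection of size a+b drawn from a+c successes, b+d failures
  p <- phyper(a - 1, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
  orr <- if (a * d == 0 && b * c == 0) NA_real_ else (a * d) / (b * c)
  list(p = p, odds_ratio = orr)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, capped at 1, returned in the input order.
#' `NA`s are preserved.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop_("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

# Signed maximum deviation of the unweighted KS-style walk for a set whose
# (sorted) hit positions in a ranking of N genes are `pos`.
es_from_positions <- function(pos, n_total, k) {
  i <- seq_len(k)
  up <- i / k - (pos - i) / (n_total - k)          # just after each hit
  down <- (i - 1) / k - (pos - i) / (n_total - k)  # just before each hit
  es_up <- max(up)
  es_down <- min(c(0, down))
  if (es_up >= abs(es_down)) es_up else es_down
}

#' GSEA-style running enrichment with permutation NES
#'
#' Unweighted (classic Kolmogorov-Smirnov) walk over a ranked gene list:
#' `+1/|S|` at set members, `-1/(N-|S|)` elsewhere. The enrichment score
#' (ES) is the signed maximum deviation of the walk, so a set occupying
#' exactly the top `k` ranks attains `ES = 1` and the bottom `k` ranks
#' `ES = -1`. The null is built from random same-size gene sets; the
#' normalised score is `NES = ES / mean(|ES_null|)` over null scores of
#' matching sign, and the permutation p-value is
#' `(1 + #\{|ES_null,same sign| >= |ES|\}) / (n_same_sign + 1)`, hence
#' never zero.
#'
#' @param ranked_genes character vector of unique gene ids, ordered by the
#'   ranking statistic.
#' @param gene_set character vector; genes absent from the ranking are
#'   dropped with a message.
#' @param n_perm number of set permutations (>= 99).
#' @param seed RNG seed for the permutations (recorded in the result).
#' @param return_curve keep the full running-score curve?
#' @return object of class `running_enrichment`: list with `es`, `nes`,
#'   `p`, `n_perm`, `seed`, `set_size`, `n_genes`, `curve` (or `NULL`),
#'   `hit_positions`.
#' @export
running_enrichment <- function(ranked_genes, gene_set, n_perm = 999,
                               seed = 1, return_curve = TRUE) {
  if (anyDuplicated(ranked_genes)) stop_("ranked_genes must be unique")
  if (n_perm < 99) stop_("n_perm must be >= 99")
  inset <- ranked_genes %in% gene_set
  dropped <- length(setdiff(gene_set, ranked_genes))
  if (dropped > 0)
    message(sprintf("running_enrichment: %d set gene(s) not in ranking dropped",
                    dropped))
  k <- sum(inset)
  n <- length(ranked_genes)
  if (k == 0) stop_("gene set empty after intersection with ranking")
  if (k == n) stop_("gene set covers the whole ranking; ES undefined")
  pos <- which(inset)
  es <- es_from_positions(pos, n, k)
  es_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      es_from_positions(sort(sample.int(n, k)), n, k)
    }, numeric(1))
  })
  same <- if (es >= 0) es_null >= 0 else es_null < 0
  n_same <- sum(same)
  nes <- if (n_same > 0) es / mean(abs(es_null[same])) else NA_real_
  p <- (1 + sum(abs(es_null[same]) >= abs(es))) / (n_same + 1)
  curve <- NULL
  if (return_curve) {
    step <- ifelse(inset, 1 / k, -1 / (n - k))
    curve <- cumsum(step)
  }
  structure(list(es = es, nes = nes, p = p, n_perm = n_perm, seed = seed,
                 set_size = k, n_genes = n, curve = curve,
                 hit_positions = pos),
            class = "running_enrichment")
}

#' @export
print.running_enrichment <- function(x, ...) {
  cat(sprintf("running enrichment: |set|=%d of %d genes; ES=%.3f NES=%.3f p=%.4g (%d perms)\n",
              x$set_size, x$n_genes, x$es, x$nes, x$p, x$n_perm))
  invisible(x)
}

# Signed significance score used to rank DE tables for RRHO:
# -log10(p) * sign(log2FC); ties broken by log2FC then gene id.
rrho_order <- function(de) {
  p <- pmax(de$p, .Machine$double.xmin)
  score <- -log10(p) * sign(de$log2fc)
  ord <- order(score, de$log2fc, de$gene_id)
  list(gene = de$gene_id[ord], score = score[ord])
}

#' Stratified rank-rank hypergeometric overlap map
#'
#' Threshold-free comparison of two differential-expression rankings. Both
#' lists are ranked by signed significance (`-log10(p) x sign(log2FC)`)
#' from the most-downregulated end; for every rank-threshold pair
#' `(i*step, j*step)` the overlap `k` between the two prefixes is scored
#' as `-log10 P(X >= k)` under the hypergeometric distribution on the
#' common universe. Cells whose two prefix ends represent concordant
#' directions (both still in the downregulated half or both past it)
#' carry positive sign; discordant cells are negative.
#'
#' @param de_a,de_b DE tables with columns `gene_id`, `log2fc`, `p`. Gene
#'   universes are intersected (dropped counts messaged).
#' @param step rank stride between grid thresholds (>= 1).
#' @return object of class `rrho_grid`: list with `grid` (signed values),
#'   `magnitude`, `thresholds`, `step`, `n_genes`.
#' @export
rrho_map <- function(de_a, de_b, step = 50) {
  if (step < 1) stop_("step must be >= 1")
  common <- intersect(de_a$gene_id, de_b$gene_id)
  if (length(common) == 0) stop_("no genes shared between the two tables")
  dropped <- nrow(de_a) + nrow(de_b) - 2 * length(common)
  if (dropped > 0)
    message(sprintf("rrho_map: %d non-shared gene entr%s dropped", dropped,
                    if (dropped == 1) "y" else "ies"))
  a <- rrho_order(de_a[de_a$gene_id %in% common, , drop = FALSE])
  b <- rrho_order(de_b[de_b$gene_id %in% common, , drop = FALSE])
  n <- length(common)
  nt <- ceiling(n / step)
  thr <- pmin(seq_len(nt) * step, n)
  rank_b <- setNames(seq_len(n), b$gene)
  # bucket counts: C[i, j] = #genes in a-stratum i and b-stratum j
  ia <- ceiling(seq_len(n) / step)
  ib <- ceiling(rank_b[a$gene] / step)
  C <- matrix(0L, nt, nt)
  for (g in seq_len(n)) C[ia[g], ib[g]] <- C[ia[g], ib[g]] + 1L
  K <- apply(apply(C, 2, cumsum), 1, cumsum)  # K[j, i] after second apply
  K <- t(K)                                   # K[i, j] = overlap at (thr_i, thr_j)
  P <- matrix(NA_real_, nt, nt)
  for (i in seq_len(nt)) {
    P[i, ] <- phyper(K[i, ] - 1, m = thr, n = n - thr, k = thr[i],
                     lower.tail = FALSE)
  }
  mag <- -log10(pmax(P, .Machine$double.xmin))
  sign_a <- ifelse(a$score[thr] <= 0, -1, 1)
  sign_b <- ifelse(b$score[thr] <= 0, -1, 1)
  conc <- outer(sign_a, sign_b, "==")
  grid <- ifelse(conc, mag, -mag)
  structure(list(grid = grid, magnitude = mag, thresholds = thr,
                 step = step, n_genes = n),
            class = "rrho_grid")
}

#' @export
print.rrho_grid <- function(x, ...) {
  cat(sprintf("RRHO grid: %dx%d thresholds (step %d) over %d genes; max |value| %.2f\n",
              nrow(x$grid), ncol(x$grid), x$step, x$n_genes,
              max(abs(x$grid))))
  invisible(x)
}
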