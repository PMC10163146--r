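# Single-cell transcriptional-consistency statistics: per-cell Shannon
# entropy after depth-equalising downsampling, per-gene Fano factors
# (variance/mean of raw counts) by cluster, and their stratification by
# promoter H3K4me3 breadth quantile.

#' Construct a single-cell expression object
#'
#' @param counts genes x cells matrix of non-negative integer counts with
#'   gene rownames and cell column names.
#' @param cluster per-cell cluster labels (length `ncol(counts)`).
#' @param pseudotime per-cell pseudotime in `[0, 1]`.
#' @return object of class `cell_expression`.
#' @export
cell_expression <- function(counts, cluster, pseudotime) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop_("counts must be non-negative")
  if (length(cluster) != ncol(counts) || length(pseudotime) != ncol(counts))
    stop_("cluster and pseudotime must have one entry per cell")
  if (any(pseudotime < 0 | pseudotime > 1))
    stop_("pseudotime must lie in [0, 1]")
  if (any(colSums(counts) == 0)) stop_("all-zero cell(s) present; filter first")
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell_%04d", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene_%04d", seq_len(nrow(counts)))
  structure(list(counts = counts, cluster = as.character(cluster),
                 pseudotime = as.numeric(pseudotime)),
            class = "cell_expression")
}

#' @export
print.cell_expression <- function(x, ...) {
  cat(sprintf("cell_expression: %d genes x %d cells, clusters: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(names(table(x$cluster)), table(x$cluster),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# Shannon entropy (bits) of a count vector's proportion vector; zero
# proportions contribute 0 by the 0 * log 0 = 0 convention.
shannon_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# Exact without-replacement downsampling of a count vector to `depth`.
downsample_counts <- function(counts, depth) {
  pool <- rep.int(seq_along(counts), counts)
  drawn <- pool[sample.int(length(pool), depth)]
  tabulate(drawn, nbins = length(counts))
}

#' Per-cell transcriptional entropy at a common depth
#'
#' Every retained cell is downsampled without replacement to
#' `target_depth` total counts and scored with the Shannon entropy (base
#' 2) of its gene-proportion vector. Downsampling removes the
#' depth-entropy confound so cluster contrasts are interpretable; cells
#' shallower than `target_depth` are dropped with a message. Entropy is
#' invariant to gene order and to appending zero-count genes, and lies in
#' `[0, log2(G)]`.
#'
#' @param cells a [cell_expression()] object.
#' @param target_depth common depth (counts) after downsampling; must be
#'   positive.
#' @param seed RNG seed for the downsampling (deterministic given seed).
#' @return `data.frame` with `cell_id`, `cluster`, `pseudotime`,
#'   `entropy` (bits), `downsampled_depth`.
#' @export
cell_entropy <- function(cells, target_depth, seed = 1) {
  stopifnot(inherits(cells, "cell_expression"))
  if (target_depth <= 0) stop_("target_depth must be > 0")
  depths <- colSums(cells$counts)
  keep <- depths >= target_depth
  if (!any(keep)) stop_("no cell reaches target_depth=%d", target_depth)
  if (any(!keep))
    message(sprintf("cell_entropy: %d cell(s) below target_depth dropped",
                    sum(!keep)))
  ent <- with_seed(seed, {
    vapply(which(keep), function(j) {
      shannon_bits(downsample_counts(cells$counts[, j], target_depth))
    }, numeric(1))
  })
  data.frame(cell_id = colnames(cells$counts)[keep],
             cluster = cells$cluster[keep],
             pseudotime = cells$pseudotime[keep],
             entropy = ent,
             downsampled_depth = target_depth,
             stringsAsFactors = FALSE)
}

#' Entropy contrast between clusters and along pseudotime
#'
#' Compares per-cell entropy between the two clusters with a Wilcoxon
#' rank-sum test and reports the Spearman correlation of entropy against
#' pseudotime over all cells.
#'
#' @param scores output of [cell_entropy()] (or any table with
#'   `entropy`, `cluster`, `pseudotime`).
#' @return list with `medians` (named per cluster), `wilcox_p`, `rho`,
#'   `rho_p`, `n`. With a single cluster the Wilcoxon entry is `NA` and a
#'   message is emitted.
#' @export
entropy_contrast <- function(scores) {
  cl <- sort(unique(scores$cluster))
  medians <- vapply(cl, function(g) median(scores$entropy[scores$cluster == g]),
                    numeric(1))
  wp <- NA_real_
  if (length(cl) < 2) {
    message("entropy_contrast: single cluster, comparison skipped")
  } else {
    x <- scores$entropy[scores$cluster == cl[1]]
    y <- scores$entropy[scores$cluster == cl[2]]
    if (length(x) < 2 || length(y) < 2) stop_("need >= 2 cells per cluster")
    wp <- suppressWarnings(wilcox.test(x, y)$p.value)
  }
  ct <- suppressWarnings(cor.test(scores$entropy, scores$pseudotime,
                                  method = "spearman"))
  list(medians = medians, wilcox_p = wp,
       rho = unname(ct$estimate), rho_p = ct$p.value, n = nrow(scores))
}

#' Per-gene Fano factors by cluster
#'
#' For each gene and cluster: mean and sample variance (n-1 denominator)
#' of raw counts across the cluster's cells, and the Fano factor
#' `variance / mean` (missing when the mean is 0; no normalisation is
#' applied). The log2 cluster-2 / cluster-1 ratio uses a small floor to
#' avoid division by zero.
#'
#' @param cells a [cell_expression()] object with exactly two clusters
#'   (>= 2 cells each). Cluster order is the sorted label order.
#' @param fano_floor floor applied to both Fano factors before the log2
#'   ratio (default 0.01).
#' @return `data.frame` with `gene_id`, `mean_1`, `var_1`, `fano_1`,
#'   `mean_2`, `var_2`, `fano_2`, `log2_fano_ratio`.
#' @export
fano_by_cluster <- function(cells, fano_floor = 0.01) {
  stopifnot(inherits(cells, "cell_expression"))
  cl <- sort(unique(cells$cluster))
  if (length(cl) != 2) stop_("need exactly two clusters, have %d", length(cl))
  if (any(table(cells$cluster) < 2)) stop_("need >= 2 cells per cluster")
  stat <- function(g) {
    m <- rowMeans(cells$counts[, cells$cluster == g, drop = FALSE])
    v <- apply(cells$counts[, cells$cluster == g, drop = FALSE], 1, var)
    fano <- ifelse(m > 0, v / m, NA_real_)
    list(m = m, v = v, fano = fano)
  }
  s1 <- stat(cl[1]); s2 <- stat(cl[2])
  ratio <- ifelse(is.na(s1$fano) | is.na(s2$fano), NA_real_,
                  log2(pmax(s2$fano, fano_floor) / pmax(s1$fano, fano_floor)))
  data.frame(gene_id = rownames(cells$counts),
             mean_1 = s1$m, var_1 = s1$v, fano_1 = s1$fano,
             mean_2 = s2$m, var_2 = s2$v, fano_2 = s2$fano,
             log2_fano_ratio = ratio, stringsAsFactors = FALSE)
}

#' Fano-ratio change as a function of promoter peak breadth
#'
#' Joins the per-gene log2 Fano ratio (cluster 2 vs cluster 1) with the
#' promoter breadth-quantile assignment and reports per-quantile mean and
#' SD plus the across-gene correlation of the ratio against breadth rank
#' (Spearman as the headline, Pearson alongside).
#'
#' @param fano output of [fano_by_cluster()].
#' @param bq a `breadth_quantiles` object with a gene map.
#' @return list with `by_quantile` (`quantile`, `n`, `mean`, `sd`),
#'   `rho`, `rho_p`, `pearson_r`, `pearson_p`, `n_genes`.
#' @export
fano_vs_breadth <- function(fano, bq) {
  gq <- gene_quantiles(bq)
  bmap <- setNames(bq$assign$breadth, bq$assign$peak_id)
  gq$breadth <- unname(bmap[bq$gene_map$peak_id])
  merged <- merge(fano[!is.na(fano$log2_fano_ratio),
                       c("gene_id", "log2_fano_ratio")],
                  gq, by = "gene_id")
  n_lost <- sum(!is.na(fano$log2_fano_ratio)) - nrow(merged)
  if (n_lost > 0)
    message(sprintf("fano_vs_breadth: %d gene(s) without quantile assignment dropped",
                    n_lost))
  pop <- unique(merged$quantile)
  if (length(pop) < 2) stop_("fewer than 2 populated quantiles")
  by_q <- do.call(rbind, lapply(sort(pop), function(q) {
    x <- merged$log2_fano_ratio[merged$quantile == q]
    data.frame(quantile = q, n = length(x), mean = mean(x), sd = sd(x))
  }))
  constant <- sd(merged$log2_fano_ratio) == 0 || sd(merged$breadth) == 0
  if (constant) {
    rho <- rp <- pr <- pp <- NA_real_
  } else {
    ct <- suppressWarnings(cor.test(merged$breadth, merged$log2_fano_ratio,
                                    method = "spearman"))
    pe <- cor.test(merged$breadth, merged$log2_fano_ratio,
                   method = "pearson")
    rho <- unname(ct$estimate); rp <- ct$p.value
    pr <- unname(pe$estimate); pp <- pe$p.value
  }
  list(by_quantile = by_q, rho = rho, rho_p = rp,
       pearson_r = pr, pearson_p = pp, n_genes = nrow(merged))
}
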