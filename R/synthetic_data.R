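# Deterministic synthetic-data generator with planted ground truth.
# Emulates the structure of a two-condition H3K4-methylation study: a
# knockout with a known global ChIP-signal depletion under an
# equal-spike-in design, promoter H3K4me3 peaks whose breadth distribution
# carries a heavy broad tail, differential expression planted
# preferentially at the extreme breadth quantiles, and two single-cell
# clusters differing in dispersion and in entropy along a pseudotime
# gradient. Every output is a pure function of the configuration (seeds
# included), and the truth tables recorded before noise suffice to score
# every downstream stage.

#' Simulation configuration
#'
#' Defaults encode the emulated study design: a knockout retaining half
#' the wild-type H3K4 methylation signal, equal spike-in depth per
#' library (10% spike share), ~5% of promoter peaks drawn from a broad
#' log-normal tail reaching ~21 kb, chromatin-state groups ii and iii at
#' roughly 15% and 1% of genes, ~4.3% of genes planted down-regulated and
#' ~1.3% up (twofold-and-more effects), down-regulation preferentially
#' coupled to the extreme breadth quantiles, and two 300-cell clusters
#' with threefold dispersion inflation and an entropy gradient along
#' pseudotime in cluster 2.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_genes,n_chroms,gene_spacing,gene_length genome layout: genes
#'   evenly spaced (`gene_spacing` bp apart) with alternating strands.
#' @param bin_width signal-track bin width in bp.
#' @param global_depletion fraction of wild-type signal remaining in the
#'   knockout, in (0, 1].
#' @param broad_tail_fraction probability a promoter H3K4me3 peak is
#'   drawn from the broad class.
#' @param breadth_log_mean,breadth_log_sd log-normal parameters of the
#'   typical breadth component (bp).
#' @param broad_log_mean,broad_log_sd log-normal parameters of the broad
#'   tail.
#' @param breadth_max breadth cap in bp; larger draws are resampled.
#' @param frac_group2,frac_group3 fractions of genes losing the H3K4me3
#'   peak but keeping H3K4me1 (group ii) or losing both (group iii) in
#'   the knockout.
#' @param signal_noise_sd per-bin multiplicative log-normal noise SD on
#'   observed tracks (0 = noise-free).
#' @param depth_sd per-library log-normal sequencing-depth SD
#'   (0 = equal depth).
#' @param spike_fraction expected spike read share of a library.
#' @param n_reps bulk RNA replicates per condition.
#' @param frac_down,frac_up planted DE fractions.
#' @param lfc_mean,lfc_sd planted |log2 fold change| distribution.
#' @param nb_dispersion negative-binomial dispersion of bulk counts.
#' @param de_min_mean minimum baseline mean for a gene to be eligible for
#'   DE planting (effects are planted at measurably expressed genes).
#' @param extreme_coupling probability a planted down gene is placed in
#'   the top or bottom breadth quantile.
#' @param q_quantiles number of breadth quantiles used for placement
#'   (matching the downstream default of 20).
#' @param global_expression_scale global knockout expression multiplier
#'   (1 = no global shift; detectable only under spike normalisation).
#' @param n_cells_per_cluster cells per single-cell cluster (0 disables
#'   the single-cell arm).
#' @param cell_depth median per-cell total counts.
#' @param cell_dispersion baseline gene-level dispersion of single-cell
#'   counts.
#' @param entropy_shift strength of the transcriptome flattening along
#'   pseudotime in cluster 2 (0 = none).
#' @param fano_inflation cluster-2 dispersion multiplier (1 = none).
#' @param fano_breadth_coupling 0..1; how strongly the cluster-2
#'   inflation increases with promoter peak breadth.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000, n_chroms = 2,
                       gene_spacing = 30000, gene_length = 2000,
                       bin_width = 50,
                       global_depletion = 0.5,
                       broad_tail_fraction = 0.05,
                       breadth_log_mean = log(1500), breadth_log_sd = 0.35,
                       broad_log_mean = log(8000), broad_log_sd = 0.45,
                       breadth_max = 21000,
                       frac_group2 = 0.15, frac_group3 = 0.01,
                       signal_noise_sd = 0.1, depth_sd = 0.1,
                       spike_fraction = 0.1,
                       n_reps = 3,
                       frac_down = 0.043, frac_up = 0.013,
                       lfc_mean = 1.5, lfc_sd = 0.3,
                       nb_dispersion = 0.01,
                       de_min_mean = 10,
                       extreme_coupling = 0.8,
                       q_quantiles = 20,
                       global_expression_scale = 1.0,
                       n_cells_per_cluster = 300,
                       cell_depth = 5000,
                       cell_dispersion = 0.3,
                       entropy_shift = 1.0,
                       fano_inflation = 3,
                       fano_breadth_coupling = 0.3) {
  cfg <- as.list(environment())
  fracs <- c(broad_tail_fraction = broad_tail_fraction,
             frac_group2 = frac_group2, frac_group3 = frac_group3,
             spike_fraction = spike_fraction, frac_down = frac_down,
             frac_up = frac_up, extreme_coupling = extreme_coupling,
             fano_breadth_coupling = fano_breadth_coupling)
  if (any(fracs < 0 | fracs > 1))
    stop_("fraction parameter outside [0, 1]: %s",
          paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  if (global_depletion <= 0 || global_depletion > 1)
    stop_("global_depletion must lie in (0, 1]")
  if (frac_group2 + frac_group3 > 1) stop_("group fractions exceed 1")
  if (n_genes < 1) stop_("n_genes must be >= 1")
  if (fano_inflation < 1) stop_("fano_inflation must be >= 1")
  structure(cfg, class = "sim_config")
}

#' Simulate a gene annotation
#'
#' Genes are evenly spaced (`gene_spacing` apart) with alternating
#' strands, split across `n_chroms` chromosomes, every TSS at the centre
#' of its slot. Deterministic given the configuration.
#'
#' @param config a [sim_config()].
#' @return gene annotation `data.frame` (all genes expressed).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  per_chrom <- ceiling(n / config$n_chroms)
  chrom_idx <- (seq_len(n) - 1L) %/% per_chrom + 1L
  slot <- (seq_len(n) - 1L) %% per_chrom
  centre <- slot * config$gene_spacing + config$gene_spacing %/% 2L
  strand <- rep_len(c("+", "-"), n)
  gl <- config$gene_length
  start <- ifelse(strand == "+", centre, centre + 1L - gl)
  end <- ifelse(strand == "+", centre + gl, centre + 1L)
  genes <- data.frame(gene_id = sprintf("gene_%05d", seq_len(n)),
                      chrom = sprintf("chr%d", chrom_idx),
                      start = as.integer(start), end = as.integer(end),
                      strand = strand,
                      tss = as.integer(centre),
                      expressed = TRUE, stringsAsFactors = FALSE)
  validate_genes(genes)
}

sim_chrom_lengths <- function(config) {
  per_chrom <- ceiling(config$n_genes / config$n_chroms)
  n_ch <- ceiling(config$n_genes / per_chrom)
  setNames(rep(per_chrom * config$gene_spacing, n_ch),
           sprintf("chr%d", seq_len(n_ch)))
}

# Draw peak breadths from the two-component log-normal mixture, resampling
# (with a message) draws below 1 bp or above the cap.
draw_breadths <- function(n, config) {
  broad <- runif(n) < config$broad_tail_fraction
  b <- ifelse(broad,
              rlnorm(n, config$broad_log_mean, config$broad_log_sd),
              rlnorm(n, config$breadth_log_mean, config$breadth_log_sd))
  n_resampled <- 0L
  for (it in 1:100) {
    bad <- b < 1 | b > config$breadth_max
    if (!any(bad)) break
    n_resampled <- n_resampled + sum(bad)
    b[bad] <- ifelse(broad[bad],
                     rlnorm(sum(bad), config$broad_log_mean, config$broad_log_sd),
                     rlnorm(sum(bad), config$breadth_log_mean, config$breadth_log_sd))
  }
  if (n_resampled > 0)
    message(sprintf("draw_breadths: %d out-of-range draw(s) resampled",
                    n_resampled))
  list(breadth = round(b), broad = broad)
}

peak_table_from <- function(genes, breadth, keep, mark, condition) {
  k <- which(keep)
  start <- pmax(0L, genes$tss[k] - breadth[k] %/% 2L)
  df <- data.frame(peak_id = sprintf("%s_%s_%s", mark, condition,
                                     genes$gene_id[k]),
                   chrom = genes$chrom[k],
                   start = as.integer(start),
                   end = as.integer(start + breadth[k]),
                   breadth = as.integer(breadth[k]),
                   mark = mark, condition = condition,
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

add_peaks_to_track <- function(values, genes, breadth, amp, keep, bin_width) {
  for (g in which(keep)) {
    ch <- genes$chrom[g]
    s <- max(0L, genes$tss[g] - breadth[g] %/% 2L)
    e <- s + breadth[g]
    i0 <- s %/% bin_width + 1L
    i1 <- min(length(values[[ch]]), ceiling(e / bin_width))
    values[[ch]][i0:i1] <- values[[ch]][i0:i1] + amp[g]
  }
  values
}

#' Simulate two-condition ChIP data with planted truth
#'
#' Every expressed gene receives a promoter H3K4me3 peak with breadth
#' drawn from a two-component log-normal mixture (typical component plus
#' broad tail) and an H3K4me1 peak. Knockout signal equals wild-type
#' signal times `global_depletion`; on top of that, group-ii genes lose
#' the H3K4me3 peak but keep H3K4me1, and group-iii genes lose both.
#' Observed tracks carry per-library depth factors and per-bin
#' multiplicative noise; spike read counts are drawn with comparable
#' expected depth in both conditions (the equal-spike-in design), so
#' spike scale factors undo depth differences while preserving the
#' global depletion.
#'
#' The truth component records, before noise: per-gene breadths, class
#' (`narrow`/`typical`/`broad`), chromatin-state group, and the realised
#' noise-free knockout/wild-type signal-mass ratio per mark
#' (`global_scale`), the quantity spike-in recovery is scored against.
#'
#' @param config a [sim_config()].
#' @param annotation output of [simulate_genome()] (or compatible).
#' @param tracks generate signal tracks and spike counts? (`FALSE` is
#'   cheaper when only peak calls are needed; peak output is unchanged.)
#' @return list with `peaks` (`peaks$H3K4me3$WT` etc.), `tracks` (same
#'   shape, `NULL` when disabled), `spike` (library table), `truth`.
#' @export
simulate_chip <- function(config, annotation, tracks = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  genes <- annotation
  n <- nrow(genes)
  out <- with_seed(derive_seed(config$seed, 1L), {
    me3 <- draw_breadths(n, config)
    me1_breadth <- round(pmin(config$breadth_max,
                              pmax(1, rlnorm(n, log(2500), 0.4))))
    u <- runif(n)
    group <- ifelse(u < config$frac_group3, "iii",
                    ifelse(u < config$frac_group3 + config$frac_group2,
                           "ii", "i"))
    me3_amp <- rlnorm(n, log(5), 0.3)
    me1_amp <- rlnorm(n, log(2), 0.3)

    keep_me3_ko <- group == "i"
    keep_me1_ko <- group %in% c("i", "ii")
    peaks <- list(
      H3K4me3 = list(
        WT = peak_table_from(genes, me3$breadth, rep(TRUE, n), "H3K4me3", "WT"),
        KO = peak_table_from(genes, me3$breadth, keep_me3_ko, "H3K4me3", "KO")),
      H3K4me1 = list(
        WT = peak_table_from(genes, me1_breadth, rep(TRUE, n), "H3K4me1", "WT"),
        KO = peak_table_from(genes, me1_breadth, keep_me1_ko, "H3K4me1", "KO")))

    gene_truth <- data.frame(
      gene_id = genes$gene_id, group = group,
      me3_breadth = as.integer(me3$breadth),
      me3_class = ifelse(me3$broad, "broad",
                         ifelse(me3$breadth < exp(config$breadth_log_mean),
                                "narrow", "typical")),
      me1_breadth = as.integer(me1_breadth),
      me3_amp = me3_amp, me1_amp = me1_amp,
      me3_peak_id = sprintf("H3K4me3_WT_%s", genes$gene_id),
      stringsAsFactors = FALSE)

    track_list <- NULL
    spike <- NULL
    global_scale <- NULL
    depth_factors <- NULL
    if (tracks) {
      bw <- config$bin_width
      lens <- sim_chrom_lengths(config)
      empty <- lapply(lens, function(L) numeric(ceiling(L / bw)))
      bg <- 0.05
      build_true <- function(breadth, amp, keep, scale) {
        v <- lapply(empty, function(x) x + bg)
        v <- add_peaks_to_track(v, genes, breadth, amp, keep, bw)
        lapply(v, function(x) x * scale)
      }
      d <- config$global_depletion
      true_tracks <- list(
        H3K4me3 = list(
          WT = build_true(me3$breadth, me3_amp, rep(TRUE, n), 1),
          KO = build_true(me3$breadth, me3_amp, keep_me3_ko, d)),
        H3K4me1 = list(
          WT = build_true(me1_breadth, me1_amp, rep(TRUE, n), 1),
          KO = build_true(me1_breadth, me1_amp, keep_me1_ko, d)))
      global_scale <- vapply(true_tracks, function(m) {
        sum(unlist(m$KO)) / sum(unlist(m$WT))
      }, numeric(1))
      lib_ids <- c("H3K4me3_WT", "H3K4me3_KO", "H3K4me1_WT", "H3K4me1_KO")
      depth_factors <- setNames(rlnorm(4, 0, config$depth_sd), lib_ids)
      observe <- function(v_true, t) {
        lapply(v_true, function(x) {
          noise <- if (config$signal_noise_sd > 0)
            rlnorm(length(x), 0, config$signal_noise_sd) else 1
          x * t * noise
        })
      }
      track_list <- list()
      spike_rows <- list()
      spike_depth0 <- 2e5 * config$spike_fraction / 0.1
      for (mark in names(true_tracks)) {
        track_list[[mark]] <- list()
        for (cond in c("WT", "KO")) {
          lid <- paste(mark, cond, sep = "_")
          vals <- observe(true_tracks[[mark]][[cond]], depth_factors[[lid]])
          track_list[[mark]][[cond]] <- signal_track(vals, bw)
          spike_noise <- if (config$depth_sd > 0 || config$signal_noise_sd > 0)
            rlnorm(1, 0, 0.02) else 1
          spike_rows[[lid]] <- data.frame(
            library_id = lid, condition = cond, mark = mark,
            target_reads = round(sum(unlist(vals))),
            spike_reads = round(spike_depth0 * depth_factors[[lid]] *
                                  spike_noise),
            stringsAsFactors = FALSE)
        }
      }
      spike <- do.call(rbind, spike_rows)
      rownames(spike) <- NULL
    }
    list(peaks = peaks, tracks = track_list, spike = spike,
         truth = list(gene = gene_truth, global_scale = global_scale,
                      depth_factors = depth_factors,
                      global_depletion = config$global_depletion))
  })
  out
}

# Breadth quantile of each gene's WT promoter H3K4me3 peak, using the
# same ranking rule as breadth_rank_quantiles so truth-level placement is
# exactly recoverable downstream.
chip_gene_quantiles <- function(chip, Q) {
  bq <- breadth_rank_quantiles(chip$peaks$H3K4me3$WT, Q = Q)
  q <- setNames(bq$assign$quantile, bq$assign$peak_id)
  setNames(unname(q[chip$truth$gene$me3_peak_id]), chip$truth$gene$gene_id)
}

#' Simulate bulk expression with DE coupled to breadth quantiles
#'
#' Counts are negative-binomial around condition means. `frac_down` of
#' genes are planted down-regulated and `frac_up` up-regulated with
#' |log2 fold changes| drawn from `N(lfc_mean, lfc_sd)`; each planted
#' down gene is placed, with probability `extreme_coupling`, at a gene
#' whose promoter H3K4me3 peak lies in the narrowest or broadest breadth
#' quantile (the truth-level placement that makes U-shaped quantile
#' enrichment an emergent property). Planting is restricted to genes
#' with baseline mean `>= de_min_mean`. Per-sample depth factors and
#' spike read counts mirror the equal-spike design.
#'
#' @param config a [sim_config()].
#' @param annotation output of [simulate_genome()].
#' @param chip_truth output of [simulate_chip()] on the same annotation
#'   (peak breadths drive the DE placement).
#' @return list with `counts` (genes x samples), `condition` labels,
#'   `spike` (per-sample spike reads), `truth` (`gene_id`, `status`,
#'   `lfc`, `mu`, `quantile`).
#' @export
simulate_bulk_expression <- function(config, annotation, chip_truth) {
  stopifnot(inherits(config, "sim_config"))
  genes <- annotation
  n <- nrow(genes)
  gq <- chip_gene_quantiles(chip_truth, config$q_quantiles)
  with_seed(derive_seed(config$seed, 2L), {
    mu <- rlnorm(n, log(50), 1.2)
    names(mu) <- genes$gene_id
    eligible <- mu >= config$de_min_mean
    n_down <- round(config$frac_down * n)
    n_up <- round(config$frac_up * n)
    status <- setNames(rep("stable", n), genes$gene_id)
    extreme <- gq[genes$gene_id] %in% c(1L, config$q_quantiles)
    pool_ext <- genes$gene_id[eligible & extreme]
    pool_mid <- genes$gene_id[eligible & !extreme]
    down <- character(0)
    for (i in seq_len(n_down)) {
      use_ext <- (runif(1) < config$extreme_coupling && length(pool_ext) > 0) ||
        length(pool_mid) == 0
      if (use_ext) {
        pick <- pool_ext[sample.int(length(pool_ext), 1)]
        pool_ext <- setdiff(pool_ext, pick)
      } else {
        pick <- pool_mid[sample.int(length(pool_mid), 1)]
        pool_mid <- setdiff(pool_mid, pick)
      }
      down <- c(down, pick)
    }
    rest <- setdiff(genes$gene_id[eligible], down)
    up <- if (n_up > 0) rest[sample.int(length(rest), min(n_up, length(rest)))]
          else character(0)
    status[down] <- "down"
    status[up] <- "up"
    lfc <- setNames(numeric(n), genes$gene_id)
    lfc[down] <- -abs(rnorm(length(down), config$lfc_mean, config$lfc_sd))
    lfc[up] <- abs(rnorm(length(up), config$lfc_mean, config$lfc_sd))

    samples <- c(sprintf("WT_%d", seq_len(config$n_reps)),
                 sprintf("KO_%d", seq_len(config$n_reps)))
    condition <- rep(c("WT", "KO"), each = config$n_reps)
    depth <- setNames(rlnorm(length(samples), 0, config$depth_sd), samples)
    counts <- matrix(0, n, length(samples),
                     dimnames = list(genes$gene_id, samples))
    size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
    for (s in seq_along(samples)) {
      m <- mu * depth[s]
      if (condition[s] == "KO")
        m <- m * 2^lfc * config$global_expression_scale
      counts[, s] <- if (is.finite(size)) rnbinom(n, mu = m, size = size)
                     else rpois(n, m)
    }
    spike0 <- 1e5
    spike <- data.frame(
      sample = samples, condition = condition,
      spike_reads = round(spike0 * depth *
                            (if (config$depth_sd > 0)
                               rlnorm(length(samples), 0, 0.02) else 1)),
      stringsAsFactors = FALSE)
    truth <- data.frame(gene_id = genes$gene_id,
                        status = unname(status[genes$gene_id]),
                        lfc = unname(lfc[genes$gene_id]),
                        mu = unname(mu[genes$gene_id]),
                        quantile = unname(gq[genes$gene_id]),
                        stringsAsFactors = FALSE)
    list(counts = counts, condition = condition, spike = spike, truth = truth)
  })
}

#' Simulate single-cell expression with an entropy gradient
#'
#' Two clusters of `n_cells_per_cluster` cells. Cluster-1 pseudotime is
#' concentrated near 0; cluster-2 pseudotime spreads towards 1. Each
#' cell's expected gene proportions derive from a common log-normal
#' baseline; in cluster 2 the proportion vector is flattened with
#' strength increasing along pseudotime (exponent
#' `1 / (1 + entropy_shift * t)`), raising transcriptional entropy, and
#' per-gene dispersion is inflated by `fano_inflation` (optionally
#' increasing with promoter peak breadth via `fano_breadth_coupling`
#' when ChIP truth is supplied). Counts are gamma-multinomial
#' (Dirichlet-multinomial-like) at a log-normal per-cell depth.
#'
#' @param config a [sim_config()].
#' @param annotation output of [simulate_genome()].
#' @param chip_truth optional [simulate_chip()] output; enables the
#'   breadth-coupled dispersion gradient.
#' @return list with `cells` (a [cell_expression()]), `truth`
#'   (per-gene baseline and cluster-2 dispersion multiplier, per-cell
#'   flatten exponent).
#' @export
simulate_cells <- function(config, annotation, chip_truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genes <- annotation
  n <- nrow(genes)
  n_cells <- config$n_cells_per_cluster
  if (n_cells < 2) stop_("n_cells_per_cluster must be >= 2")
  with_seed(derive_seed(config$seed, 3L), {
    base_mu <- rlnorm(n, log(50), 1.2)
    r <- if (!is.null(chip_truth)) {
      rank(chip_truth$truth$gene$me3_breadth, ties.method = "average") / n
    } else rep(0.5, n)
    cc <- config$fano_breadth_coupling
    infl <- 2^(log2(config$fano_inflation) * (1 - cc + 2 * cc * r))
    cluster <- rep(c("cluster1", "cluster2"), each = n_cells)
    t1 <- rbeta(n_cells, 1.2, 12)
    t2 <- rbeta(n_cells, 2.5, 1.5)
    pseudotime <- pmin(1, c(t1, t2))
    exponent <- ifelse(cluster == "cluster2",
                       1 / (1 + config$entropy_shift * pseudotime), 1)
    depth <- pmax(100L, round(rlnorm(2 * n_cells, log(config$cell_depth), 0.2)))
    counts <- matrix(0L, n, 2 * n_cells,
                     dimnames = list(genes$gene_id,
                                     sprintf("%s_c%04d", cluster,
                                             seq_len(2 * n_cells))))
    for (j in seq_len(2 * n_cells)) {
      phi <- config$cell_dispersion *
        (if (cluster[j] == "cluster2") infl else 1)
      w <- base_mu^exponent[j] * rgamma(n, shape = 1 / phi, rate = 1 / phi)
      counts[, j] <- rmultinom(1, depth[j], w / sum(w))
    }
    cells <- cell_expression(counts, cluster, pseudotime)
    truth <- list(base_mu = setNames(base_mu, genes$gene_id),
                  inflation = setNames(infl, genes$gene_id),
                  exponent = exponent,
                  entropy_shift = config$entropy_shift,
                  fano_inflation = config$fano_inflation)
    list(cells = cells, truth = truth)
  })
}
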