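# Spike-in (ChIP-Rx style) normalisation. A fixed amount of foreign-cell
# chromatin (or a fixed spike-cell proportion for RNA) is added to every
# library, so the spike read count measures per-cell sequencing yield and
# global signal differences between conditions survive normalisation --
# unlike equal-total scaling, which erases them by construction.

#' Spike-in scale factors (reference-to-minimum convention)
#'
#' `scale_factor_j = min_k(spike_reads_k) / spike_reads_j`, so the library
#' with the smallest spike depth keeps factor 1 and every other library is
#' scaled down. Downscale-only factors never inflate noise.
#'
#' Factors are invariant to multiplying all spike counts by a constant.
#'
#' @param libraries `data.frame` with at least `library_id` and
#'   `spike_reads` columns (one row per library).
#' @return the input with a `scale_factor` column filled in.
#' @export
spike_scale_factors <- function(libraries) {
  stopifnot(is.data.frame(libraries), nrow(libraries) >= 1)
  if (!all(c("library_id", "spike_reads") %in% names(libraries)))
    stop_("libraries needs library_id and spike_reads columns")
  if (any(libraries$spike_reads <= 0))
    stop_("spike_reads must be > 0 for every library (normalization undefined)")
  libraries$scale_factor <- min(libraries$spike_reads) / libraries$spike_reads
  libraries
}

#' Apply a scale factor to a signal track
#'
#' Every bin is multiplied by `factor`; the factor is recorded on the track
#' and re-scaling an already scaled track is an error.
#'
#' @param track an unscaled `signal_track`.
#' @param factor positive scale factor (typically from
#'   [spike_scale_factors()]).
#' @return the scaled `signal_track`.
#' @export
apply_scaling <- function(track, factor) {
  stopifnot(inherits(track, "signal_track"))
  if (isTRUE(track$scaled))
    stop_("track is already scaled (factor %.4g); refusing to re-scale",
          track$scale_factor)
  if (!is.numeric(factor) || factor <= 0) stop_("scale factor must be > 0")
  track$values <- lapply(track$values, function(v) v * factor)
  track$scaled <- TRUE
  track$scale_factor <- factor
  track
}

#' Spike-normalised expression matrix
#'
#' Cell-equivalent scaling: each column is divided by its spike read count
#' and multiplied by the mean spike count, yielding counts-per-spike-read
#' on a common scale. Column totals are free to differ between samples, so
#' a global expression change between conditions is preserved (per-column
#' total-count scaling would erase it).
#'
#' @param counts genes x samples matrix of raw counts.
#' @param spike_counts numeric vector of spike reads, one per sample
#'   (recycled names checked against `colnames(counts)` when both named).
#' @return matrix of spike-normalised counts, same shape as `counts`.
#' @export
normalized_expression <- function(counts, spike_counts) {
  stopifnot(is.matrix(counts))
  if (length(spike_counts) != ncol(counts))
    stop_("need one spike count per sample (%d != %d)",
          length(spike_counts), ncol(counts))
  if (any(spike_counts <= 0)) stop_("zero or negative spike count")
  if (!is.null(names(spike_counts)) && !is.null(colnames(counts))) {
    if (!all(colnames(counts) %in% names(spike_counts)))
      stop_("spike_counts names do not cover all samples")
    spike_counts <- spike_counts[colnames(counts)]
  }
  sweep(counts, 2, spike_counts / mean(spike_counts), "/")
}

#' Genome-wide signal ratio between two tracks
#'
#' Ratio of total track areas (numerator over denominator), the statistic
#' used to measure global signal depletion after spike scaling.
#'
#' @param track_num,track_den `signal_track`s on the same genome.
#' @return numeric scalar `area(track_num) / area(track_den)`.
#' @export
global_signal_ratio <- function(track_num, track_den) {
  signal_area(track_num) / signal_area(track_den)
}
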