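# Readers/writers for the plain-text formats the pipeline touches.
# One coordinate convention everywhere: 0-based, half-open (BED-style).
# GTF input (1-based, inclusive) is converted at this boundary and never
# leaks past it.

VALID_MARKS <- c("H3K4me3", "H3K4me1", "H3K27ac", "H3K27me3")

validate_genes <- function(genes) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "tss", "expressed")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0) stop_("gene annotation missing column(s): %s",
                              paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop_("duplicate gene_id in annotation: %s",
          genes$gene_id[duplicated(genes$gene_id)][1])
  if (any(genes$start < 0) || any(genes$start >= genes$end))
    stop_("gene annotation violates 0 <= start < end")
  if (!all(genes$strand %in% c("+", "-")))
    stop_("strand must be '+' or '-'")
  tss_expect <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  if (any(genes$tss != tss_expect))
    stop_("tss inconsistent with start/end/strand for gene %s",
          genes$gene_id[which(genes$tss != tss_expect)[1]])
  genes
}

#' Read a gene annotation (GTF-lite or TSV)
#'
#' GTF input is 1-based inclusive and is converted to the package-internal
#' 0-based half-open convention on read; only `gene` feature lines are used.
#' TSV input is either the full seven-column table written by
#' [write_gene_annotation()] (already 0-based) or a minimal four-column
#' table `gene_id, chrom, tss, strand`, in which case each gene becomes a
#' 1 bp record anchored at its TSS.
#'
#' The TSS is derived strand-aware: `start` for `+` genes, `end - 1` for
#' `-` genes.
#'
#' @param path path to the annotation file.
#' @param format `"tsv"` or `"gtf"`.
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `expressed` (0-based half-open coordinates).
#' @export
read_gene_annotation <- function(path, format = c("tsv", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("annotation file not found: %s", path)
  genes <- if (format == "gtf") read_gtf_genes(path) else read_tsv_genes(path)
  validate_genes(genes)
}

read_gtf_genes <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  out <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9)
      stop_("malformed GTF line %d: expected 9 tab-separated fields, got %d",
            i, length(f))
    if (f[3] != "gene") next
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1))
      stop_("malformed GTF line %d: non-numeric coordinates", i)
    m <- regmatches(f[9], regexec('gene_id[ =]+"?([^";]+)"?', f[9]))[[1]]
    if (length(m) < 2)
      stop_("malformed GTF line %d: no gene_id attribute", i)
    out[[length(out) + 1L]] <- data.frame(
      gene_id = m[2], chrom = f[1],
      start = start1 - 1L, end = end1, strand = f[7],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE)
  } else {
    genes <- do.call(rbind, out)
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$expressed <- TRUE
  genes
}

read_tsv_genes <- function(path) {
  genes <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (all(c("start", "end") %in% names(genes))) {
    if (!"tss" %in% names(genes))
      genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  } else if ("tss" %in% names(genes)) {
    genes$start <- as.integer(genes$tss)
    genes$end <- genes$start + 1L
  } else {
    stop_("TSV annotation needs either start/end or tss columns")
  }
  if (!"expressed" %in% names(genes)) genes$expressed <- TRUE
  genes$expressed <- as.logical(genes$expressed)
  genes[c("gene_id", "chrom", "start", "end", "strand", "tss", "expressed")]
}

#' Write a gene annotation as TSV
#'
#' @param genes annotation `data.frame` as returned by
#'   [read_gene_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  validate_genes(genes)
  write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read peak calls from a BED file
#'
#' BED is 0-based half-open and is kept as-is. Peaks are sorted by
#' `(chrom, start, end)`; overlapping peaks are *not* merged so that
#' downstream breadth statistics see the caller's output unchanged. If the
#' file has a fourth column it is used as `peak_id`, otherwise stable ids
#' are assigned after sorting.
#'
#' @param path BED3+ file. An empty file yields an empty peak table.
#' @param mark histone mark label attached to all peaks.
#' @param condition condition label attached to all peaks.
#' @return `data.frame` with columns `peak_id`, `chrom`, `start`, `end`,
#'   `breadth`, `mark`, `condition`.
#' @export
read_peaks <- function(path, mark = "H3K4me3", condition = "WT") {
  if (!file.exists(path)) stop_("peak file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) return(empty_peaks(mark, condition))
  tab <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  pk <- data.frame(chrom = as.character(tab[[1]]),
                   start = as.integer(tab[[2]]),
                   end = as.integer(tab[[3]]),
                   stringsAsFactors = FALSE)
  if (any(pk$start >= pk$end))
    stop_("peak with start >= end at input row %d", which(pk$start >= pk$end)[1])
  pk$peak_id <- if (ncol(tab) >= 4) as.character(tab[[4]]) else NA_character_
  pk <- pk[order(pk$chrom, pk$start, pk$end), , drop = FALSE]
  if (anyNA(pk$peak_id))
    pk$peak_id <- sprintf("%s_%s_peak_%05d", mark, condition, seq_len(nrow(pk)))
  if (anyDuplicated(pk$peak_id))
    stop_("duplicate peak_id within (%s, %s)", mark, condition)
  rownames(pk) <- NULL
  data.frame(peak_id = pk$peak_id, chrom = pk$chrom, start = pk$start,
             end = pk$end, breadth = pk$end - pk$start,
             mark = mark, condition = condition, stringsAsFactors = FALSE)
}

empty_peaks <- function(mark = "H3K4me3", condition = "WT") {
  data.frame(peak_id = character(), chrom = character(), start = integer(),
             end = integer(), breadth = integer(),
             mark = character(), condition = character(),
             stringsAsFactors = FALSE)
}

#' Write peaks as BED4
#'
#' Writes the sorted normal form (chrom, start, end order), so
#' `write_peaks(read_peaks(x))` is idempotent.
#'
#' @param peaks peak `data.frame` from [read_peaks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  write.table(peaks[c("chrom", "start", "end", "peak_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a binned signal track
#'
#' A signal track is a dense fixed-bin representation of non-negative ChIP
#' signal: one numeric vector per chromosome, bin `i` covering
#' `[(i-1)*bin_width, i*bin_width)`.
#'
#' @param values named list of non-negative numeric vectors, one per
#'   chromosome.
#' @param bin_width bin width in base pairs.
#' @param scaled logical; has a spike-in scale factor been applied?
#' @param scale_factor the factor applied (1 when unscaled).
#' @return object of class `signal_track`.
#' @export
signal_track <- function(values, bin_width, scaled = FALSE, scale_factor = 1) {
  stopifnot(is.list(values), !is.null(names(values)), bin_width >= 1)
  if (any(vapply(values, function(v) any(v < 0), logical(1))))
    stop_("signal track values must be non-negative")
  structure(list(values = values, bin_width = as.integer(bin_width),
                 scaled = scaled, scale_factor = scale_factor),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chromosome(s), bin_width=%d bp, %s (factor %.4g)\n",
              length(x$values), x$bin_width,
              if (x$scaled) "spike-scaled" else "unscaled", x$scale_factor))
  invisible(x)
}

#' Total area of a signal track
#'
#' Sum of bin values times bin width, i.e. the integral of the track.
#'
#' @param track a `signal_track`.
#' @return numeric scalar.
#' @export
signal_area <- function(track) {
  sum(vapply(track$values, sum, numeric(1))) * track$bin_width
}

#' Read a bedGraph file into a binned signal track
#'
#' Intervals must start and end on multiples of `bin_width`; anything else
#' is an error (no silent resampling). Regions absent from the file are 0.
#'
#' @param path bedGraph file (chrom, start, end, value).
#' @param bin_width bin width in base pairs that the intervals tile.
#' @param chrom_lengths optional named vector of chromosome lengths in bp;
#'   when omitted each chromosome extends to the last covered interval.
#' @return a `signal_track`.
#' @export
read_signal <- function(path, bin_width, chrom_lengths = NULL) {
  if (!file.exists(path)) stop_("bedGraph file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0 && is.null(chrom_lengths))
    stop_("empty bedGraph and no chrom_lengths given: cannot size track")
  tab <- if (length(lines)) {
    read.table(text = lines, sep = "\t", stringsAsFactors = FALSE,
               col.names = c("chrom", "start", "end", "value"))
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               value = numeric())
  }
  bad <- which(tab$start %% bin_width != 0 | tab$end %% bin_width != 0)
  if (length(bad) > 0)
    stop_("bedGraph interval not aligned to bin_width=%d at data row %d",
          bin_width, bad[1])
  if (any(tab$value < 0)) stop_("negative signal in bedGraph")
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else unique(tab$chrom)
  values <- list()
  for (ch in chroms) {
    sub <- tab[tab$chrom == ch, , drop = FALSE]
    len_bp <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else max(sub$end)
    n_bins <- ceiling(len_bp / bin_width)
    v <- numeric(n_bins)
    if (nrow(sub) > 0) {
      for (r in seq_len(nrow(sub))) {
        i0 <- sub$start[r] %/% bin_width + 1L
        i1 <- sub$end[r] %/% bin_width
        v[i0:i1] <- sub$value[r]
      }
    }
    values[[ch]] <- v
  }
  signal_track(values, bin_width)
}

#' Write a signal track as bedGraph
#'
#' Runs of equal value are merged into single intervals; zero-valued runs
#' are omitted (the bedGraph convention), so trailing-zero track length is
#' not preserved unless `chrom_lengths` is passed back to [read_signal()].
#'
#' @param track a `signal_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  bw <- track$bin_width
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (length(v) == 0) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    df <- data.frame(ch, starts[keep] * bw, ends[keep] * bw,
                     format(r$values[keep], digits = 10, scientific = FALSE,
                            trim = TRUE))
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a counts matrix (genes x samples) from TSV
#'
#' @param path TSV with a header row of sample ids and gene ids in the
#'   first column.
#' @return integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a counts matrix as TSV
#'
#' @param counts matrix with gene rownames and sample column names.
#' @param path output path.
#' @param header optional character vector of `#`-prefixed comment lines
#'   written before the table (provenance).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT-like file
#'
#' One set per line: `set_name <tab> gene1 <tab> gene2 ...`. A second
#' description column (classic GMT) is tolerated when it does not look like
#' a gene id already present in another set.
#'
#' @param path gene-set file.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop_("gene-set line with no genes: %s", f[1])
    sets[[f[1]]] <- unique(f[-1])
  }
  sets
}

#' Write gene sets in the GMT-like one-set-per-line format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read single-cell expression (MTX + metadata)
#'
#' @param mtx_path MatrixMarket file of counts (genes x cells).
#' @param features_path one gene id per line, matching MTX rows.
#' @param meta_path TSV with columns `cell_id`, `cluster`, `pseudotime`,
#'   rows matching MTX columns.
#' @return a [cell_expression()] object.
#' @export
read_cell_expression <- function(mtx_path, features_path, meta_path) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  features <- readLines(features_path)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(m) != length(features))
    stop_("MTX has %d rows but %d features listed", nrow(m), length(features))
  if (ncol(m) != nrow(meta))
    stop_("MTX has %d columns but %d metadata rows", ncol(m), nrow(meta))
  rownames(m) <- features
  colnames(m) <- meta$cell_id
  cell_expression(m, cluster = meta$cluster, pseudotime = meta$pseudotime)
}

#' Write single-cell expression as MTX + metadata TSVs
#'
#' @param cells a [cell_expression()] object.
#' @param mtx_path,features_path,meta_path output paths.
#' @return `mtx_path`, invisibly.
#' @export
write_cell_expression <- function(cells, mtx_path, features_path, meta_path) {
  Matrix::writeMM(Matrix::Matrix(cells$counts, sparse = TRUE), mtx_path)
  writeLines(rownames(cells$counts), features_path)
  meta <- data.frame(cell_id = colnames(cells$counts),
                     cluster = cells$cluster,
                     pseudotime = cells$pseudotime)
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mtx_path)
}
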