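## Binned coverage tracks.
##
## A coverage_track holds one numeric vector of per-bin values per
## chromosome, the bin size, the total mapped read count and the units
## (raw counts or RPKM). Bin i (1-based) covers [ (i-1)*bin_size,
## i*bin_size ) on the chromosome.

#' Construct a binned coverage track
#'
#' @param bins Named list, one numeric vector of per-bin values per
#'   chromosome.
#' @param bin_size Bin width in bp.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param total_mapped Total mapped reads backing the track; used by
#'   [rpkm_normalize()]. Defaults to the sum over bins.
#' @param units `"raw"` (counts) or `"RPKM"`.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(bins, bin_size, chrom_lengths = NULL,
                           total_mapped = NULL, units = "raw") {
  stopifnot_scalar_number(bin_size, "bin_size", 0, strict_min = TRUE)
  if (!is.list(bins) || is.null(names(bins)) || any(!nzchar(names(bins))))
    stop("'bins' must be a named list of per-chromosome numeric vectors",
         call. = FALSE)
  bins <- lapply(bins, as.numeric)
  if (any(vapply(bins, function(b) any(b < 0), logical(1))))
    stop("bin values must be >= 0", call. = FALSE)
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(bins, length, numeric(1)) * bin_size
  if (is.null(total_mapped))
    total_mapped <- sum(vapply(bins, sum, numeric(1)))
  units <- match.arg(units, c("raw", "RPKM"))
  if (units == "RPKM" && total_mapped <= 0)
    stop("RPKM track requires total_mapped > 0", call. = FALSE)
  structure(list(bins = bins, bin_size = bin_size,
                 chrom_lengths = chrom_lengths[names(bins)],
                 total_mapped = total_mapped, units = units),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d chromosome(s), bin_size %d bp, units %s\n",
              length(x$bins), as.integer(x$bin_size), x$units))
  cat(sprintf("  bins: %s; total_mapped: %s\n",
              format(sum(lengths(x$bins)), big.mark = ","),
              format(x$total_mapped, big.mark = ",")))
  invisible(x)
}

#' Bin reads into a coverage track
#'
#' Each read is assigned to exactly one bin by its 5' position (`start`
#' on the `+` strand, `end - 1` on the `-` strand; a bare `pos` column is
#' used as-is). Reads beyond the chromosome bounds are clipped into the
#' terminal bin with a warning, so the total assigned equals the number
#' of reads.
#'
#' @param reads data.frame with columns `chrom` and either `pos` or
#'   `start`/`end` (+ optional `strand`).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param bin_size Bin width in bp.
#' @param total_mapped Total mapped reads; defaults to `nrow(reads)`.
#' @return A raw-unit `coverage_track`.
#' @export
bin_coverage <- function(reads, chrom_lengths, bin_size,
                         total_mapped = nrow(reads)) {
  stopifnot_scalar_number(bin_size, "bin_size", 0, strict_min = TRUE)
  if (is.null(names(chrom_lengths)))
    stop("'chrom_lengths' must be named by chromosome", call. = FALSE)
  if ("pos" %in% names(reads)) {
    pos <- reads$pos
  } else {
    strand <- reads$strand %||% rep("+", nrow(reads))
    pos <- ifelse(strand == "-", reads$end - 1, reads$start)
  }
  n_bins <- ceiling(chrom_lengths / bin_size)
  bins <- lapply(n_bins, numeric)
  clipped <- 0L
  for (ch in unique(as.character(reads$chrom))) {
    if (!ch %in% names(chrom_lengths))
      stop("read on unknown chromosome: ", ch, call. = FALSE)
    p <- pos[reads$chrom == ch]
    out_of_bounds <- p < 0 | p >= chrom_lengths[[ch]]
    clipped <- clipped + sum(out_of_bounds)
    p <- pmin(pmax(p, 0), chrom_lengths[[ch]] - 1)
    idx <- floor(p / bin_size) + 1L
    tab <- tabulate(idx, nbins = n_bins[[ch]])
    bins[[ch]] <- bins[[ch]] + tab
  }
  if (clipped > 0)
    warning(clipped, " read(s) beyond chromosome bounds were clipped")
  coverage_track(bins, bin_size, chrom_lengths,
                 total_mapped = total_mapped, units = "raw")
}

#' RPKM-normalize a coverage track
#'
#' Converts raw per-bin counts to reads per kilobase per million mapped
#' reads: `count / (bin_size/1000) / (total_mapped/1e6)`. The transform
#' is linear and invertible given `total_mapped`.
#'
#' @param track Raw-unit `coverage_track` with `total_mapped > 0`.
#' @return A `coverage_track` with `units = "RPKM"`.
#' @export
rpkm_normalize <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$units != "raw")
    stop("track is already normalized (units = ", track$units, ")",
         call. = FALSE)
  if (track$total_mapped <= 0)
    stop("cannot RPKM-normalize: total_mapped must be > 0", call. = FALSE)
  f <- 1 / (track$bin_size / 1000) / (track$total_mapped / 1e6)
  track$bins <- lapply(track$bins, function(b) b * f)
  track$units <- "RPKM"
  track
}

#' Mean signal over an interval
#'
#' Averages bin values over an interval; bins partially covered by the
#' interval are weighted by the fraction of the bin the interval covers,
#' so the result equals the per-base mean of the piecewise-constant
#' signal.
#'
#' @param track A `coverage_track`.
#' @param chrom,start,end Interval in 0-based half-open coordinates.
#' @return The weighted mean signal (in the track's units).
#' @export
mean_signal <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "coverage_track"))
  if (!chrom %in% names(track$bins))
    stop("no such chromosome in track: ", chrom, call. = FALSE)
  if (end <= start) stop("zero-length interval", call. = FALSE)
  b <- track$bins[[chrom]]
  bs <- track$bin_size
  L <- length(b) * bs
  if (start < 0 || end > L)
    stop(sprintf("interval [%s, %s) outside track bounds [0, %s)",
                 start, end, L), call. = FALSE)
  i0 <- floor(start / bs) + 1L
  i1 <- ceiling(end / bs)
  idx <- i0:i1
  lo <- pmax((idx - 1) * bs, start)
  hi <- pmin(idx * bs, end)
  w <- hi - lo
  sum(b[idx] * w) / sum(w)
}

# Vectorized mean_signal over an interval data.frame; returns NA (with
# the out-of-bounds attribute set) for intervals outside track bounds.
interval_means <- function(track, intervals) {
  n <- nrow(intervals)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    out[i] <- tryCatch(
      mean_signal(track, intervals$chrom[i], intervals$start[i],
                  intervals$end[i]),
      error = function(e) NA_real_)
  }
  out
}

#' Read and write bedGraph coverage tracks
#'
#' `write_bedgraph()` writes the track as runs of constant value;
#' `read_bedgraph()` reads a bedGraph back into per-bin values given the
#' bin size (bedGraph interval boundaries must align with bins).
#'
#' @param track A `coverage_track`.
#' @param path File path.
#' @param bin_size Bin width of the track being read.
#' @param chrom_lengths Named chromosome lengths; defaults to the extent
#'   covered by the file.
#' @param total_mapped Total mapped reads of the track being read;
#'   defaults to the sum over bins.
#' @param units Units of the values in the file.
#' @return `read_bedgraph()` returns a `coverage_track`;
#'   `write_bedgraph()` returns `path` invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  pieces <- lapply(names(track$bins), function(ch) {
    b <- track$bins[[ch]]
    r <- rle(b)
    ends <- cumsum(r$lengths) * track$bin_size
    starts <- c(0, ends[-length(ends)])
    ends <- pmin(ends, track$chrom_lengths[[ch]])
    data.frame(chrom = ch, start = starts, end = ends, value = r$values,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end),
                               score = df$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, bin_size, chrom_lengths = NULL,
                          total_mapped = NULL, units = "raw") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "bedGraph")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr) - 1
  end <- GenomicRanges::end(gr)
  if (any(start %% bin_size != 0))
    stop("bedGraph intervals do not align with bin_size ", bin_size,
         call. = FALSE)
  chroms <- unique(chrom)
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(chroms, function(ch) max(end[chrom == ch]),
                            numeric(1))
  bins <- lapply(chroms, function(ch) {
    numeric(ceiling(chrom_lengths[[ch]] / bin_size))
  })
  names(bins) <- chroms
  for (i in seq_along(gr)) {
    ch <- chrom[i]
    i0 <- start[i] / bin_size + 1
    i1 <- ceiling(end[i] / bin_size)
    bins[[ch]][i0:i1] <- gr$score[i]
  }
  coverage_track(bins, bin_size, chrom_lengths,
                 total_mapped = total_mapped, units = units)
}
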