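## Enriched-region (peak) calling on binned coverage.
##
## A deliberately small local-Poisson caller: each bin is tested against a
## background rate lambda = max(genome-wide mean, local mean in a sliding
## window), and runs of significant adjacent bins are joined into peaks.
## This mirrors the common local-lambda strategy of ChIP-seq peak callers
## at bin resolution; it is not a re-implementation of any of them.

#' Call enriched regions on a raw coverage track
#'
#' Per-bin upper-tail Poisson p-values are computed against a background
#' rate `lambda = max(genome-wide mean, local mean)` where the local mean
#' is taken over a centered window (`local_window` bp, default 10 kb).
#' Adjacent significant bins (`p < p_cutoff`) are joined into peaks; the
#' summit is the maximal bin (first such bin on ties) and the reported
#' peak p-value is the minimum over its bins.
#'
#' @param track Raw-count `coverage_track`.
#' @param p_cutoff Per-bin significance cutoff (default 0.001).
#' @param local_window Width in bp of the local background window.
#' @return A peak data.frame: interval columns plus `p_value`, `summit`
#'   (bp position of the summit bin start) and `max_count`.
#' @export
call_peaks <- function(track, p_cutoff = 0.001, local_window = 10000) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$units != "raw")
    stop("call_peaks expects raw counts, not ", track$units, call. = FALSE)
  stopifnot_scalar_number(p_cutoff, "p_cutoff", 0, strict_min = TRUE)
  if (p_cutoff >= 1) stop("'p_cutoff' must be < 1", call. = FALSE)
  all_bins <- unlist(track$bins, use.names = FALSE)
  lambda_global <- mean(all_bins)
  out <- list()
  if (lambda_global > 0) {
    half <- max(1L, floor(local_window / track$bin_size / 2))
    for (ch in names(track$bins)) {
      x <- track$bins[[ch]]
      lambda_local <- running_mean(x, half)
      lambda <- pmax(lambda_global, lambda_local)
      p <- ppois(x - 1, lambda, lower.tail = FALSE)
      sig <- p < p_cutoff
      if (!any(sig)) next
      r <- rle(sig)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- which(r$values)
      peaks <- lapply(keep, function(k) {
        i0 <- starts[k]; i1 <- ends[k]
        seg <- x[i0:i1]
        s <- i0 + which.max(seg) - 1L
        data.frame(chrom = ch,
                   start = (i0 - 1) * track$bin_size,
                   end = min(i1 * track$bin_size, track$chrom_lengths[[ch]]),
                   p_value = min(p[i0:i1]),
                   summit = (s - 1) * track$bin_size,
                   max_count = max(seg),
                   stringsAsFactors = FALSE)
      })
      out[[ch]] <- do.call(rbind, peaks)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(), score = numeric(),
                      strand = character(), p_value = numeric(),
                      summit = numeric(), max_count = numeric(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  res <- genomic_intervals(df$chrom, df$start, df$end,
                           name = sprintf("peak_%d", seq_len(nrow(df))),
                           score = -log10(pmax(df$p_value, 1e-300)))
  res$p_value <- df$p_value
  res$summit <- df$summit
  res$max_count <- df$max_count
  res
}

# Centered running mean with half-width k bins; edges use the available
# (truncated) window.
running_mean <- function(x, k) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - k, 1)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Merge intervals closer than a gap threshold
#'
#' Intervals whose gap (`next start - previous end`) is strictly less
#' than `max_gap` are merged, transitively; overlapping and bookended
#' (gap 0) intervals always merge. The operation is idempotent.
#'
#' @param intervals Interval data.frame.
#' @param max_gap Gap threshold in bp (default 500: merge when gap < 500).
#' @return Sorted, merged interval data.frame; the `score` column counts
#'   the number of input intervals merged into each output interval.
#' @export
merge_close_peaks <- function(intervals, max_gap = 500) {
  intervals <- validate_intervals(intervals)
  stopifnot_scalar_number(max_gap, "max_gap", 0)
  if (!nrow(intervals)) return(intervals)
  o <- order(intervals$chrom, intervals$start, intervals$end)
  df <- intervals[o, , drop = FALSE]
  pieces <- lapply(split(df, df$chrom), function(d) {
    n <- nrow(d)
    if (n == 1L) grp <- 1L
    else {
      prev_max_end <- cummax(d$end)[-n]
      gap <- d$start[-1] - prev_max_end
      ## merge when gap < max_gap; overlapping or bookended intervals
      ## (gap <= 0) always merge
      new_run <- c(TRUE, gap >= max(max_gap, 1))
      grp <- cumsum(new_run)
    }
    data.frame(chrom = d$chrom[1],
               start = tapply(d$start, grp, min),
               end = tapply(d$end, grp, max),
               n_merged = as.numeric(table(grp)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, pieces)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  out <- genomic_intervals(res$chrom, res$start, res$end,
                           score = res$n_merged)
  out$name <- interval_id(out)
  out
}

#' Select putative enhancer intervals
#'
#' Takes the union of H3K4me1 peaks from both conditions and removes any
#' peak that overlaps an H3K4me3 peak or lies within `tss_exclusion` bp
#' of a TSS (interval-to-TSS distance, 0 when the TSS falls inside the
#' peak), leaving distal H3K4me1-high / H3K4me3-low regions.
#'
#' @param k4me1_peaks_a,k4me1_peaks_b H3K4me1 peak intervals for the two
#'   conditions.
#' @param k4me3_peaks H3K4me3 peak intervals (promoter mark) used for
#'   exclusion.
#' @param genes Gene-model data.frame supplying TSS positions.
#' @param tss_exclusion Distance in bp around TSSs to exclude (default
#'   2000).
#' @param mode Combine condition peak sets by `"union"` (default) or
#'   `"intersection"` (keep regions with an H3K4me1 peak in both).
#' @return Interval data.frame of putative enhancers (unmerged; see
#'   [merge_close_peaks()]).
#' @export
select_putative_enhancers <- function(k4me1_peaks_a, k4me1_peaks_b,
                                      k4me3_peaks, genes,
                                      tss_exclusion = 2000,
                                      mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  a <- validate_intervals(k4me1_peaks_a)
  b <- validate_intervals(k4me1_peaks_b)
  pool <- rbind(a[, 1:6], b[, 1:6])
  if (mode == "intersection") {
    keep <- overlaps_any(pool, a) & overlaps_any(pool, b)
    pool <- pool[keep, , drop = FALSE]
  }
  ## collapse duplicates / overlaps from the two conditions
  pool <- merge_close_peaks(pool, max_gap = 0)
  if (!nrow(pool)) return(pool)
  drop_k4me3 <- overlaps_any(pool, validate_intervals(k4me3_peaks))
  near_tss <- vapply(seq_len(nrow(pool)), function(i) {
    tss <- genes$tss[genes$chrom == pool$chrom[i]]
    if (!length(tss)) return(FALSE)
    ## distance from the peak interval to the nearest TSS (0 if inside)
    d <- pmax(0, pmax(pool$start[i] - tss, tss - (pool$end[i] - 1)))
    min(d) <= tss_exclusion
  }, logical(1))
  out <- pool[!(drop_k4me3 | near_tss), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach per-mark, per-condition signal to catalog intervals
#'
#' For every interval, computes the mean signal (see [mean_signal()]) in
#' each supplied track and stores it as a `signal_<mark>_<condition>`
#' column. Intervals falling outside a track's bounds are flagged and
#' excluded with a warning.
#'
#' @param intervals Catalog interval data.frame (merged enhancers).
#' @param tracks Nested named list `tracks[[mark]][[condition]]` of
#'   RPKM-normalized `coverage_track` objects.
#' @return An `enhancer_catalog`: the interval data.frame with signal
#'   columns and `marks`/`conditions` attributes.
#' @export
attach_signal <- function(intervals, tracks) {
  intervals <- validate_intervals(intervals)
  if (!length(tracks)) stop("no tracks supplied", call. = FALSE)
  marks <- names(tracks)
  conditions <- names(tracks[[1]])
  for (m in marks) {
    if (!identical(names(tracks[[m]]), conditions))
      stop("all marks must cover the same conditions", call. = FALSE)
    for (cond in conditions) {
      tr <- tracks[[m]][[cond]]
      if (!inherits(tr, "coverage_track"))
        stop("tracks[['", m, "']][['", cond, "']] is not a coverage_track",
             call. = FALSE)
      if (tr$units != "RPKM")
        warning("track ", m, "/", cond, " is not RPKM-normalized")
    }
  }
  out <- intervals
  if (!nrow(out)) {
    for (m in marks) for (cond in conditions)
      out[[paste("signal", m, cond, sep = "_")]] <- numeric(0)
  } else {
    for (m in marks) for (cond in conditions)
      out[[paste("signal", m, cond, sep = "_")]] <-
        interval_means(tracks[[m]][[cond]], intervals)
  }
  sig_cols <- grep("^signal_", names(out), value = TRUE)
  bad <- Reduce(`|`, lapply(sig_cols, function(cn) is.na(out[[cn]])),
                rep(FALSE, nrow(out)))
  if (any(bad)) {
    warning(sum(bad), " interval(s) outside track bounds excluded from catalog")
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) && (is.null(out$name) || any(is.na(out$name))))
    out$name <- interval_id(out)
  rownames(out) <- NULL
  structure(out, marks = marks, conditions = conditions,
            class = c("enhancer_catalog", "data.frame"))
}
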