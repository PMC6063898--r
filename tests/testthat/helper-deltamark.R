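# Shared fixtures and independent oracles used across test files.

# random interval sets on a small namespace, for merge/select oracles
random_interval_set <- function(n, n_chrom = 2, max_pos = 10000,
                                max_len = 800) {
  chrom <- sample(sprintf("chr%d", seq_len(n_chrom)), n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  genomic_intervals(chrom, start, start + len)
}

# O(n^2) transitive-closure merge oracle: repeatedly fuse any two
# intervals on the same chromosome with gap < max_gap until stable
brute_force_merge <- function(df, max_gap) {
  items <- split(df, seq_len(nrow(df)))
  repeat {
    fused <- FALSE
    for (i in seq_along(items)) {
      if (fused) break
      for (j in seq_along(items)) {
        if (i >= j) next
        a <- items[[i]]; b <- items[[j]]
        if (a$chrom != b$chrom) next
        gap <- max(a$start, b$start) - min(a$end, b$end)
        if (gap < max(max_gap, 1)) {  # gap <= 0 (overlap/bookend) always fuses
          items[[i]]$start <- min(a$start, b$start)
          items[[i]]$end <- max(a$end, b$end)
          items[[j]] <- NULL
          fused <- TRUE
          break
        }
      }
    }
    if (!fused) break
  }
  out <- do.call(rbind, items)
  out <- out[order(out$chrom, out$start), c("chrom", "start", "end")]
  rownames(out) <- NULL
  out
}

# adjusted Rand index between two label vectors (closed form from the
# pair-counting contingency table)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# constant-value coverage track
constant_track <- function(value, n_bins = 100, bin_size = 50,
                           chrom = "chr1", units = "raw") {
  coverage_track(setNames(list(rep(value, n_bins)), chrom), bin_size,
                 total_mapped = max(1, value * n_bins), units = units)
}

# small scenario used by pipeline-level tests (fast to simulate)
small_scenario_args <- function(seed = 1) {
  list(genome_length = 1e6, n_genes = 30, n_enhancers = 80,
       n_activated = 10, seed = seed)
}

# precision/recall of a called enhancer group against planted truth,
# matched by interval overlap
group_precision_recall <- function(group_intervals, scenario) {
  truth <- scenario$enhancers[
    scenario$enhancers$name %in% scenario$truth$activated_set, ,
    drop = FALSE]
  list(precision = mean(deltamark:::overlaps_any(group_intervals, truth)),
       recall = mean(deltamark:::overlaps_any(truth, group_intervals)))
}
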