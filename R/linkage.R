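## Enhancer-to-gene linkage and differential expression.

#' Nearest gene by TSS distance
#'
#' Assigns each enhancer the gene (on the same chromosome) whose TSS is
#' closest to the enhancer midpoint. Ties are broken by lower TSS
#' coordinate, then lexicographic `gene_id`. Translation of all
#' coordinates by a constant leaves assignments unchanged.
#'
#' @param enhancers Interval data.frame.
#' @param genes Gene-model data.frame (non-empty).
#' @return data.frame with `enhancer_id`, `gene_id`, `distance` (bp from
#'   enhancer midpoint to TSS). Enhancers on chromosomes without genes
#'   are dropped with a warning.
#' @export
nearest_gene <- function(enhancers, genes) {
  if (!nrow(genes)) stop("empty gene list", call. = FALSE)
  enhancers <- validate_intervals(enhancers)
  ids <- enhancers$name
  if (any(is.na(ids))) ids <- interval_id(enhancers)
  mid <- floor((enhancers$start + enhancers$end) / 2)
  out <- vector("list", nrow(enhancers))
  for (i in seq_len(nrow(enhancers))) {
    g <- genes[genes$chrom == enhancers$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    d <- abs(g$tss - mid[i])
    o <- order(d, g$tss, g$gene_id)
    out[[i]] <- data.frame(enhancer_id = ids[i],
                           gene_id = g$gene_id[o[1]],
                           distance = d[o[1]],
                           stringsAsFactors = FALSE)
  }
  missing <- vapply(out, is.null, logical(1))
  if (any(missing))
    warning(sum(missing),
            " enhancer(s) on chromosomes without genes dropped")
  res <- do.call(rbind, out[!missing])
  rownames(res) <- NULL
  res
}

#' Library-size-normalized expression fold change
#'
#' Computes per-gene `fc = (count_B/libsize_B + eps) /
#' (count_A/libsize_A + eps)` where `eps` is a small pseudo-fraction
#' (default 1e-6 of the mean normalized count) guarding against division
#' by zero. Genes absent from one table are excluded with a warning.
#'
#' @param counts_a,counts_b Named numeric vectors of gene counts.
#' @param libsize_a,libsize_b Library sizes; default to the column sums.
#' @param pseudo_frac Pseudo-fraction of the mean normalized count.
#' @return Named vector of fold changes (condition B over A).
#' @export
expression_fold_change <- function(counts_a, counts_b,
                                   libsize_a = sum(counts_a),
                                   libsize_b = sum(counts_b),
                                   pseudo_frac = 1e-6) {
  if (libsize_a <= 0 || libsize_b <= 0)
    stop("library sizes must be > 0", call. = FALSE)
  common <- intersect(names(counts_a), names(counts_b))
  dropped <- length(counts_a) + length(counts_b) - 2 * length(common)
  if (dropped > 0)
    warning(dropped, " gene record(s) absent from one table excluded")
  a <- counts_a[common] / libsize_a
  b <- counts_b[common] / libsize_b
  eps <- pseudo_frac * mean(c(a, b))
  fc <- (b + eps) / (a + eps)
  names(fc) <- common
  fc
}

#' Exact per-gene differential-expression p-values
#'
#' With a single library per condition, tests each gene's condition-B
#' count against its total using the conditional binomial: given
#' `n = count_A + count_B`, under the null `count_B ~ Binomial(n, p0)`
#' with `p0 = libsize_B / (libsize_A + libsize_B)`. Two-sided p-values
#' use the minimum-likelihood method of [stats::binom.test()]. Genes
#' with zero total count get p = 1.
#'
#' @param counts_a,counts_b Named numeric count vectors over the same
#'   genes.
#' @param libsize_a,libsize_b Library sizes (default: sums).
#' @return Named vector of two-sided p-values.
#' @export
de_significance <- function(counts_a, counts_b,
                            libsize_a = sum(counts_a),
                            libsize_b = sum(counts_b)) {
  common <- intersect(names(counts_a), names(counts_b))
  a <- round(counts_a[common])
  b <- round(counts_b[common])
  p0 <- libsize_b / (libsize_a + libsize_b)
  p <- vapply(seq_along(common), function(i) {
    n <- a[i] + b[i]
    if (n == 0) return(1)
    binom.test(b[i], n, p = p0)$p.value
  }, numeric(1))
  names(p) <- common
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin named wrapper around
#' [stats::p.adjust()] so the linkage table's adjusted column has a
#' single documented provenance.
#'
#' @param p_values Numeric vector of p-values.
#' @return Adjusted p-values (same order and names).
#' @export
adjust_bh <- function(p_values) {
  p.adjust(p_values, method = "BH")
}

#' Rank genes linked to an enhancer group by fold change
#'
#' Restricts the enhancer-gene links to a group of enhancers (e.g. the
#' activated group), deduplicates genes (keeping the closest linking
#' enhancer), sorts by fold change descending (ties broken by
#' `gene_id`), and returns the top rows.
#'
#' @param group Character vector of enhancer identifiers.
#' @param links Link table from [nearest_gene()].
#' @param fold_changes,p_values,adjusted_p Named per-gene vectors.
#' @param top_n Number of rows to keep (default 10; `Inf` for all).
#' @return data.frame with columns `rank`, `gene_id`, `fold_change`,
#'   `log2_fold_change`, `p_value`, `adjusted_p`, `enhancer_id`,
#'   `distance`.
#' @export
rank_group_genes <- function(group, links, fold_changes, p_values,
                             adjusted_p, top_n = 10) {
  sel <- links[links$enhancer_id %in% group, , drop = FALSE]
  if (!nrow(sel)) {
    return(data.frame(rank = integer(), gene_id = character(),
                      fold_change = numeric(), log2_fold_change = numeric(),
                      p_value = numeric(), adjusted_p = numeric(),
                      enhancer_id = character(), distance = numeric(),
                      stringsAsFactors = FALSE))
  }
  sel <- sel[order(sel$gene_id, sel$distance), , drop = FALSE]
  sel <- sel[!duplicated(sel$gene_id), , drop = FALSE]
  sel <- sel[sel$gene_id %in% names(fold_changes), , drop = FALSE]
  fc <- fold_changes[sel$gene_id]
  o <- order(-fc, sel$gene_id)
  sel <- sel[o, , drop = FALSE]
  fc <- fc[o]
  n <- min(nrow(sel), top_n)
  idx <- seq_len(n)
  data.frame(rank = idx,
             gene_id = sel$gene_id[idx],
             fold_change = unname(fc[idx]),
             log2_fold_change = unname(log2(fc[idx])),
             p_value = unname(p_values[sel$gene_id[idx]]),
             adjusted_p = unname(adjusted_p[sel$gene_id[idx]]),
             enhancer_id = sel$enhancer_id[idx],
             distance = sel$distance[idx],
             stringsAsFactors = FALSE)
}
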