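## Enhancer-state clustering: log2 ratio matrix, k-means, activated-group
## selection, aggregate metaprofiles.

#' Compute the per-enhancer log2 signal-ratio matrix
#'
#' For each catalog interval and each mark, computes
#' `log2((signal_B + pseudocount) / (signal_A + pseudocount))`. The
#' pseudocount (RPKM units) keeps entries finite; when both signals are
#' zero the entry is exactly 0. Swapping the conditions negates every
#' entry.
#'
#' @param catalog An `enhancer_catalog` from [attach_signal()].
#' @param condition_a,condition_b Condition labels (ratio is B over A).
#' @param pseudocount Stabilizing constant in signal units (default 0.5).
#' @param marks Marks to include; defaults to H3K4me1 and H3K27ac.
#' @return Numeric matrix with one row per enhancer (rownames = enhancer
#'   names) and one `log2_ratio_<mark>` column per mark.
#' @export
compute_ratio_matrix <- function(catalog, condition_a = "A",
                                 condition_b = "B", pseudocount = 0.5,
                                 marks = c("H3K4me1", "H3K27ac")) {
  stopifnot_scalar_number(pseudocount, "pseudocount", 0)
  cols_a <- paste("signal", marks, condition_a, sep = "_")
  cols_b <- paste("signal", marks, condition_b, sep = "_")
  miss <- setdiff(c(cols_a, cols_b), names(catalog))
  if (length(miss))
    stop("catalog lacks signal columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- vapply(seq_along(marks), function(i) {
    a <- catalog[[cols_a[i]]]
    b <- catalog[[cols_b[i]]]
    ifelse(a == 0 & b == 0, 0,
           log2((b + pseudocount) / (a + pseudocount)))
  }, numeric(nrow(catalog)))
  m <- matrix(m, nrow = nrow(catalog),
              dimnames = list(catalog$name,
                              paste0("log2_ratio_", marks)))
  m
}

#' k-means clustering of the ratio matrix
#'
#' Deterministic k-means with k-means++ seeding: for each of `nstart`
#' restarts initial centers are drawn by the k-means++ rule under the
#' given seed, Lloyd iterations are run to convergence, and the solution
#' with the lowest total within-cluster sum of squares is kept.
#' Degenerate inputs with fewer distinct rows than `k` are assigned one
#' cluster per distinct row (remaining clusters empty).
#'
#' @param mat Numeric matrix (rows = enhancers).
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed controlling the initialization.
#' @param nstart Number of k-means++ restarts (default 10).
#' @return List with `labels` (named integer vector in `1..k`),
#'   `centroids` (`k x ncol` matrix, `NA` rows for empty clusters) and
#'   `tot_withinss`.
#' @export
kmeans_cluster <- function(mat, k = 4, seed = 1, nstart = 10) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (k < 2) stop("'k' must be >= 2", call. = FALSE)
  if (nrow(mat) < k)
    stop("fewer rows (", nrow(mat), ") than clusters (", k, ")",
         call. = FALSE)
  if (any(!is.finite(mat))) stop("ratio matrix has non-finite entries",
                                 call. = FALSE)
  uniq <- unique(mat)
  if (nrow(uniq) < k) {
    ## degenerate: one cluster per distinct row, the rest left empty
    key <- apply(mat, 1, paste, collapse = "\r")
    ukey <- unique(key)
    labels <- match(key, ukey)
    centroids <- matrix(NA_real_, nrow = k, ncol = ncol(mat),
                        dimnames = list(NULL, colnames(mat)))
    centroids[seq_len(nrow(uniq)), ] <- uniq
    names(labels) <- rownames(mat)
    return(list(labels = labels, centroids = centroids,
                tot_withinss = 0))
  }
  best <- NULL
  local_seed(seed, {
    for (r in seq_len(nstart)) {
      centers <- kmeanspp_init(mat, k)
      fit <- suppressWarnings(
        kmeans(mat, centers = centers, iter.max = 100, algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  labels <- best$cluster
  names(labels) <- rownames(mat)
  centroids <- best$centers
  dimnames(centroids) <- list(NULL, colnames(mat))
  list(labels = labels, centroids = centroids,
       tot_withinss = best$tot.withinss)
}

# k-means++ seeding: first center uniform, subsequent centers sampled
# with probability proportional to squared distance to the nearest
# chosen center.
kmeanspp_init <- function(mat, k) {
  n <- nrow(mat)
  centers <- matrix(NA_real_, k, ncol(mat))
  idx <- sample.int(n, 1)
  centers[1, ] <- mat[idx, ]
  d2 <- rowSums((mat - rep(centers[1, ], each = n))^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = d2)
    centers[j, ] <- mat[idx, ]
    d2 <- pmin(d2, rowSums((mat - rep(centers[j, ], each = n))^2))
  }
  ## ensure distinct centers (duplicates break stats::kmeans)
  dup <- duplicated(centers)
  while (any(dup)) {
    pool <- which(!duplicated(mat))
    idx <- sample(pool, sum(dup))
    centers[dup, ] <- mat[idx, , drop = FALSE]
    dup <- duplicated(centers)
  }
  centers
}

#' Select the activated enhancer group
#'
#' The activated ("Group-1") enhancers are the members of every cluster
#' whose centroid is positive in all ratio dimensions — both H3K4me1 and
#' H3K27ac gained in condition B. Selection is rule-based on the
#' centroids rather than on a cluster index, so it is robust to the
#' choice of `k`: if k-means splits the gaining enhancers into several
#' clusters (e.g. primed-to-active versus inactive-to-active, which gain
#' the marks to different degrees), all of them are selected. If no
#' centroid is positive in all coordinates an empty set is returned with
#' a warning.
#'
#' @param labels Named cluster labels from [kmeans_cluster()].
#' @param centroids Centroid matrix from [kmeans_cluster()].
#' @param min_gain Minimal centroid log2 gain required in every
#'   dimension (default 0: strictly positive).
#' @return Character vector of enhancer identifiers in the activated
#'   group, ordered as in `labels`.
#' @export
select_activated_group <- function(labels, centroids, min_gain = 0) {
  min_coord <- apply(centroids, 1, function(z) {
    if (any(!is.finite(z))) -Inf else min(z)
  })
  sel <- which(min_coord > min_gain)
  if (!length(sel)) {
    warning("no cluster centroid is positive in all ratio dimensions; ",
            "returning an empty activated group")
    return(character(0))
  }
  names(labels)[labels %in% sel]
}

#' Aggregate signal metaprofile around anchors
#'
#' Averages track signal across a set of anchors in one of three modes:
#' `"center"` (offsets from interval centers), `"tss"` (offsets from
#' gene TSSs, minus-strand profiles reversed so downstream of the TSS is
#' always to the right), and `"scaled"` (each gene body resampled from
#' TSS to TTS onto a fixed number of positions by linear interpolation,
#' then averaged). Anchors whose window extends beyond the track are
#' dropped with a warning.
#'
#' @param track A `coverage_track`.
#' @param anchors Interval data.frame (`"center"` mode) or gene-model
#'   data.frame (`"tss"`/`"scaled"` modes).
#' @param mode Profile mode.
#' @param window Half-window in bp for anchored modes (default 5000).
#' @param n_points Number of resampled positions for `"scaled"` mode.
#' @return A data.frame with `position` (bp offset, or scaled fraction
#'   in `[0,1]` for `"scaled"`) and `mean_signal`; attribute `n_anchors`
#'   records the number of anchors used.
#' @export
metaprofile <- function(track, anchors, mode = c("center", "tss", "scaled"),
                        window = 5000, n_points = 100) {
  mode <- match.arg(mode)
  stopifnot(inherits(track, "coverage_track"))
  if (!nrow(anchors)) stop("no anchors supplied", call. = FALSE)
  bs <- track$bin_size
  if (mode %in% c("center", "tss")) {
    offsets <- seq(-window, window, by = bs)
    centers <- if (mode == "center") {
      floor((anchors$start + anchors$end) / 2)
    } else {
      if (is.null(anchors$tss)) stop("tss mode needs gene models",
                                     call. = FALSE)
      anchors$tss
    }
    flip <- if (mode == "tss") anchors$strand == "-" else
      rep(FALSE, nrow(anchors))
    rows <- vector("list", nrow(anchors))
    for (i in seq_len(nrow(anchors))) {
      ch <- anchors$chrom[i]
      if (!ch %in% names(track$bins)) next
      b <- track$bins[[ch]]
      pos <- centers[i] + offsets
      if (pos[1] < 0 || pos[length(pos)] >= length(b) * bs) next
      v <- b[floor(pos / bs) + 1]
      if (flip[i]) v <- rev(v)
      rows[[i]] <- v
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
      stop("no anchors fall fully within the track", call. = FALSE)
    if (length(rows) < nrow(anchors))
      warning(nrow(anchors) - length(rows),
              " anchor(s) outside track bounds dropped")
    prof <- colMeans(do.call(rbind, rows))
    out <- data.frame(position = offsets, mean_signal = prof)
  } else {
    if (is.null(anchors$tss) || is.null(anchors$tts))
      stop("scaled mode needs gene models with tss/tts", call. = FALSE)
    rows <- vector("list", nrow(anchors))
    for (i in seq_len(nrow(anchors))) {
      ch <- anchors$chrom[i]
      if (!ch %in% names(track$bins)) next
      b <- track$bins[[ch]]
      i0 <- floor(anchors$start[i] / bs) + 1
      i1 <- ceiling(anchors$end[i] / bs)
      if (i0 < 1 || i1 > length(b)) next
      v <- b[i0:i1]
      if (anchors$strand[i] == "-") v <- rev(v)
      if (length(v) == 1) rows[[i]] <- rep(v, n_points)
      else rows[[i]] <- approx(seq_along(v), v, n = n_points)$y
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
      stop("no anchors fall fully within the track", call. = FALSE)
    if (length(rows) < nrow(anchors))
      warning(nrow(anchors) - length(rows),
              " anchor(s) outside track bounds dropped")
    prof <- colMeans(do.call(rbind, rows))
    out <- data.frame(position = seq(0, 1, length.out = n_points),
                      mean_signal = prof)
  }
  attr(out, "n_anchors") <- length(rows)
  attr(out, "mode") <- mode
  out
}
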