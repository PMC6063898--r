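## The core differential enhancer-activation analysis, exposed in the
## classic modelling idiom: one fitting function returning a classed
## object with print/summary/plot/coef methods.

#' Differential enhancer-activation analysis
#'
#' Given an enhancer catalog carrying per-mark, per-condition signal and
#' RNA-seq counts for the two conditions, computes the per-enhancer
#' log2(B/A) ratio matrix for H3K4me1 and H3K27ac, clusters it by
#' k-means, selects the activated group (the cluster gaining both
#' marks), links every enhancer to its nearest-TSS gene and ranks the
#' activated group's genes by expression fold change with exact binomial
#' p-values and Benjamini-Hochberg adjustment.
#'
#' @param catalog An `enhancer_catalog` from [attach_signal()].
#' @param genes Gene-model data.frame.
#' @param counts_a,counts_b Named per-gene RNA-seq count vectors for
#'   conditions A and B.
#' @param k Number of k-means clusters (default 4).
#' @param pseudocount Ratio pseudocount in RPKM units (default 0.5).
#' @param condition_a,condition_b Condition labels in the catalog.
#' @param seed Seed for the k-means initialization.
#' @param nstart k-means restarts.
#' @param top_n Rows kept in the ranked gene table (default 10).
#' @return An object of class `enhancer_activation` with components
#'   `ratio_matrix`, `labels`, `centroids`, `activated` (enhancer ids),
#'   `links`, `fold_changes`, `p_values`, `adjusted_p`, `gene_table`
#'   (the ranked table) and `call`.
#' @seealso [run_pipeline()] for the file-based end-to-end driver.
#' @export
enhancer_activation <- function(catalog, genes, counts_a, counts_b,
                                k = 4, pseudocount = 0.5,
                                condition_a = "A", condition_b = "B",
                                seed = 1, nstart = 10, top_n = 10) {
  ratio <- compute_ratio_matrix(catalog, condition_a, condition_b,
                                pseudocount = pseudocount)
  cl <- kmeans_cluster(ratio, k = k, seed = seed, nstart = nstart)
  activated <- select_activated_group(cl$labels, cl$centroids)
  links <- nearest_gene(catalog, genes)
  fc <- expression_fold_change(counts_a, counts_b)
  p <- de_significance(counts_a, counts_b)
  padj <- adjust_bh(p)
  tab <- rank_group_genes(activated, links, fc, p, padj, top_n = top_n)
  structure(list(ratio_matrix = ratio, labels = cl$labels,
                 centroids = cl$centroids,
                 tot_withinss = cl$tot_withinss,
                 activated = activated, links = links,
                 fold_changes = fc, p_values = p, adjusted_p = padj,
                 gene_table = tab, k = k, pseudocount = pseudocount,
                 call = match.call()),
            class = "enhancer_activation")
}

#' @export
print.enhancer_activation <- function(x, ...) {
  cat("Differential enhancer-activation analysis\n")
  cat(sprintf("  %d enhancers clustered (k = %d); activated group: %d\n",
              nrow(x$ratio_matrix), x$k, length(x$activated)))
  if (nrow(x$gene_table)) {
    cat("  top activated-group genes by fold change:\n")
    tp <- head(x$gene_table[, c("rank", "gene_id", "fold_change",
                                "p_value", "adjusted_p")], 5)
    tp$fold_change <- signif(tp$fold_change, 4)
    tp$p_value <- signif(tp$p_value, 3)
    tp$adjusted_p <- signif(tp$adjusted_p, 3)
    print(tp, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.enhancer_activation <- function(object, ...) {
  sizes <- table(factor(object$labels, levels = seq_len(object$k)))
  cents <- round(object$centroids, 3)
  out <- list(n_enhancers = nrow(object$ratio_matrix),
              k = object$k, cluster_sizes = as.integer(sizes),
              centroids = cents,
              n_activated = length(object$activated),
              n_genes_ranked = nrow(object$gene_table),
              gene_table = object$gene_table)
  class(out) <- "summary.enhancer_activation"
  out
}

#' @export
print.summary.enhancer_activation <- function(x, ...) {
  cat("Enhancer-activation summary\n")
  cat(sprintf("  enhancers: %d, clusters: %d, activated: %d\n",
              x$n_enhancers, x$k, x$n_activated))
  cat("  cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  cat("  centroids (log2 B/A):\n")
  print(x$centroids)
  cat(sprintf("  ranked activated-group genes: %d\n", x$n_genes_ranked))
  if (nrow(x$gene_table)) print(x$gene_table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.enhancer_activation <- function(object, ...) object$centroids

#' Scatter plot of the enhancer ratio matrix
#'
#' Plots log2 H3K27ac ratio against log2 H3K4me1 ratio, coloured by
#' cluster, with the activated group highlighted.
#'
#' @param x An `enhancer_activation` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.enhancer_activation <- function(x, ...) {
  m <- x$ratio_matrix
  cols <- hcl.colors(x$k, "Dark 2")[x$labels]
  plot(m[, 1], m[, 2], col = cols, pch = 16, cex = 0.5,
       xlab = colnames(m)[1], ylab = colnames(m)[2], ...)
  abline(h = 0, v = 0, lty = 3, col = "grey50")
  act <- rownames(m) %in% x$activated
  if (any(act)) points(m[act, 1], m[act, 2], pch = 1, cex = 0.9)
  invisible(x)
}
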