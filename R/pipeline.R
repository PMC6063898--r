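## End-to-end pipeline: simulate/load -> peaks -> catalog -> cluster ->
## link, with a manifest and deterministic text outputs.

#' Validate and normalize a pipeline configuration
#'
#' Fills documented defaults, checks units and ranges, and rejects
#' contradictory options with an aggregated, human-readable error.
#' A configuration either names input files (`tracks`, `annotation`,
#' `counts`) or requests a synthetic scenario (`scenario = TRUE`, plus
#' any [scenario_config()] overrides in `scenario_args`).
#'
#' @param config Named list of options. Recognized fields: `scenario`,
#'   `scenario_args`, `tracks` (named list
#'   `tracks[[mark]][[condition]]` of bedGraph paths), `annotation`,
#'   `counts` (TSV paths), `bin_size`, `p_cutoff` (default 0.001),
#'   `merge_gap` (default 500), `tss_exclusion` (default 2000),
#'   `pseudocount` (default 0.5), `k` (default 4), `seed` (default 1),
#'   `top_n` (default 10), `peak_mode` (`"union"`/`"intersection"`).
#' @return The normalized configuration list.
#' @export
validate_config <- function(config = list()) {
  defaults <- list(scenario = FALSE, scenario_args = list(),
                   tracks = NULL, annotation = NULL, counts = NULL,
                   bin_size = 50, p_cutoff = 0.001, merge_gap = 500,
                   tss_exclusion = 2000, pseudocount = 0.5, k = 4,
                   seed = 1, top_n = 10, peak_mode = "union")
  unknown <- setdiff(names(config), names(defaults))
  errors <- character(0)
  if (length(unknown))
    errors <- c(errors, paste("unknown option(s):",
                              paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config[intersect(names(config),
                                                      names(defaults))])
  chk <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  chk(is.numeric(cfg$p_cutoff) && cfg$p_cutoff > 0 && cfg$p_cutoff < 1,
      "p_cutoff must be in (0, 1)")
  chk(is.numeric(cfg$merge_gap) && cfg$merge_gap >= 0,
      "merge_gap must be >= 0")
  chk(is.numeric(cfg$tss_exclusion) && cfg$tss_exclusion >= 0,
      "tss_exclusion must be >= 0")
  chk(is.numeric(cfg$pseudocount) && cfg$pseudocount >= 0,
      "pseudocount must be >= 0")
  chk(is.numeric(cfg$k) && cfg$k >= 2, "k must be >= 2 for clustering")
  chk(is.numeric(cfg$bin_size) && cfg$bin_size > 0, "bin_size must be > 0")
  chk(is.numeric(cfg$top_n) && cfg$top_n >= 1, "top_n must be >= 1")
  chk(cfg$peak_mode %in% c("union", "intersection"),
      "peak_mode must be 'union' or 'intersection'")
  if (!isTRUE(cfg$scenario)) {
    if (is.null(cfg$tracks) || is.null(cfg$annotation) ||
        is.null(cfg$counts))
      errors <- c(errors, paste("without scenario = TRUE the config must",
                                "name 'tracks', 'annotation' and 'counts'"))
    for (p in c(unlist(cfg$tracks), cfg$annotation, cfg$counts))
      if (!is.null(p) && !file.exists(p))
        errors <- c(errors, paste("missing input file:", p))
  } else if (!is.null(cfg$tracks)) {
    errors <- c(errors, "give either scenario = TRUE or file inputs, not both")
  }
  if (length(errors))
    stop("invalid pipeline configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  cfg
}

#' Run the full enhancer-activation pipeline
#'
#' Simulates or loads the inputs, calls H3K4me1/H3K4me3 peaks in both
#' conditions, builds the merged distal-enhancer catalog with attached
#' RPKM signal, fits [enhancer_activation()], and writes the result
#' bundle: catalog BED, ratio-matrix TSV with cluster labels, activated
#' group BED, ranked gene table TSV, TSS/center metaprofile TSVs and a
#' JSON run manifest. Outputs are deterministic for a fixed
#' configuration and seed.
#'
#' @param config Pipeline configuration (see [validate_config()]).
#' @param output_dir Directory for the result bundle.
#' @param quiet Suppress stage-by-stage progress messages.
#' @return The fitted `enhancer_activation` object, invisibly, with the
#'   written `paths` and the `scenario` (when synthetic) attached as
#'   attributes.
#' @export
run_pipeline <- function(config = list(scenario = TRUE), output_dir,
                         quiet = FALSE) {
  cfg <- validate_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  scenario <- NULL
  if (isTRUE(cfg$scenario)) {
    stage("simulate", {
      sc_args <- cfg$scenario_args
      if (is.null(sc_args$seed)) sc_args$seed <- cfg$seed
      if (is.null(sc_args$bin_size)) sc_args$bin_size <- cfg$bin_size
      scenario <- do.call(scenario_config, sc_args)
      scenario <- make_genome(scenario)
      tracks <- simulate_mark_tracks(scenario)
      counts_df <- simulate_rnaseq(scenario)
      genes <- scenario$genes
      say("simulate: %d genes, %d enhancers (%d activated)",
          nrow(genes), nrow(scenario$enhancers),
          length(scenario$truth$activated_set))
    })
  } else {
    stage("load", {
      genes <- read_annotation(cfg$annotation)
      tracks <- lapply(cfg$tracks, function(conds)
        lapply(conds, read_bedgraph, bin_size = cfg$bin_size))
      counts_df <- read.delim(cfg$counts, stringsAsFactors = FALSE)
      say("load: %d genes, %d track(s)", nrow(genes),
          sum(lengths(cfg$tracks)))
    })
  }
  counts_a <- setNames(counts_df$count_A, counts_df$gene_id)
  counts_b <- setNames(counts_df$count_B, counts_df$gene_id)

  peaks <- list()
  stage("peaks", {
    for (m in c("H3K4me1", "H3K4me3")) {
      if (!m %in% names(tracks))
        stop("no ", m, " tracks available")
      peaks[[m]] <- lapply(tracks[[m]], call_peaks,
                           p_cutoff = cfg$p_cutoff)
    }
    say("peaks: H3K4me1 %d (A) / %d (B); H3K4me3 %d (A) / %d (B)",
        nrow(peaks$H3K4me1$A), nrow(peaks$H3K4me1$B),
        nrow(peaks$H3K4me3$A), nrow(peaks$H3K4me3$B))
  })

  stage("catalog", {
    k4me3_all <- merge_close_peaks(rbind(peaks$H3K4me3$A[, 1:6],
                                         peaks$H3K4me3$B[, 1:6]),
                                   max_gap = 0)
    putative <- select_putative_enhancers(peaks$H3K4me1$A,
                                          peaks$H3K4me1$B, k4me3_all,
                                          genes,
                                          tss_exclusion = cfg$tss_exclusion,
                                          mode = cfg$peak_mode)
    merged <- merge_close_peaks(putative, max_gap = cfg$merge_gap)
    rpkm <- lapply(tracks, function(conds) lapply(conds, rpkm_normalize))
    catalog <- attach_signal(merged, rpkm[c("H3K4me1", "H3K27ac")])
    say("catalog: %d putative -> %d merged enhancers",
        nrow(putative), nrow(catalog))
  })

  stage("cluster+link", {
    fit <- enhancer_activation(catalog, genes, counts_a, counts_b,
                               k = cfg$k, pseudocount = cfg$pseudocount,
                               seed = cfg$seed, top_n = cfg$top_n)
    say("cluster+link: %d enhancers in activated group; top gene %s",
        length(fit$activated),
        if (nrow(fit$gene_table)) fit$gene_table$gene_id[1] else "<none>")
  })

  paths <- list()
  stage("write", {
    paths$catalog_bed <- write_bed(catalog,
                                   file.path(output_dir, "catalog.bed"))
    rm_df <- data.frame(enhancer_id = rownames(fit$ratio_matrix),
                        fit$ratio_matrix,
                        cluster = unname(fit$labels),
                        activated = rownames(fit$ratio_matrix) %in%
                          fit$activated,
                        check.names = FALSE)
    paths$ratio_matrix <- file.path(output_dir, "ratio_matrix.tsv")
    write.table(rm_df, paths$ratio_matrix, sep = "\t", quote = FALSE,
                row.names = FALSE)
    grp <- catalog[catalog$name %in% fit$activated, , drop = FALSE]
    paths$group1_bed <- write_bed(grp[, c("chrom", "start", "end", "name",
                                          "score", "strand")],
                                  file.path(output_dir, "group1.bed"))
    paths$gene_table <- file.path(output_dir, "ranked_genes.tsv")
    write.table(fit$gene_table, paths$gene_table, sep = "\t",
                quote = FALSE, row.names = FALSE)
    mp_tss <- metaprofile(tracks$H3K4me1$B, genes, mode = "tss")
    mp_center <- metaprofile(tracks$H3K4me1$B, catalog, mode = "center")
    paths$metaprofile_tss <- file.path(output_dir, "metaprofile_tss.tsv")
    write.table(mp_tss, paths$metaprofile_tss, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths$metaprofile_center <- file.path(output_dir,
                                          "metaprofile_center.tsv")
    write.table(mp_center, paths$metaprofile_center, sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest <- list(
      package = "deltamark",
      version = as.character(packageVersion("deltamark")),
      config = cfg[c("bin_size", "p_cutoff", "merge_gap", "tss_exclusion",
                     "pseudocount", "k", "seed", "top_n", "peak_mode",
                     "scenario")],
      counts = list(
        peaks_k4me1_a = nrow(peaks$H3K4me1$A),
        peaks_k4me1_b = nrow(peaks$H3K4me1$B),
        peaks_k4me3 = nrow(k4me3_all),
        catalog = nrow(catalog),
        clustered = nrow(fit$ratio_matrix),
        activated = length(fit$activated),
        genes_ranked = nrow(fit$gene_table)))
    paths$manifest <- file.path(output_dir, "manifest.json")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    say("write: %d artifact(s) in %s", length(paths), output_dir)
  })

  attr(fit, "paths") <- paths
  attr(fit, "scenario") <- scenario
  invisible(fit)
}
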