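## Synthetic two-condition epigenome scenarios with planted ground truth.
##
## The generator emulates the statistical structure the analysis assumes:
## a genome with non-overlapping genes and intergenic enhancers, each
## enhancer in a chromatin state (active / primed / poised / inactive)
## per condition; a planted "activated" subset switches to the active
## state in condition B. Histone-mark tracks are Poisson counts over
## state-dependent enrichment footprints; RNA-seq counts are negative
## binomial with fold-change effects planted on genes nearest activated
## enhancers, coupling mark gain to expression gain the way the analysis
## expects to see it.

#' Scenario configuration for the synthetic generator
#'
#' @param genome_length Total genome length in bp (default 10 Mb).
#' @param n_chromosomes Number of equally sized chromosomes (default 1).
#' @param bin_size Coverage bin width in bp (default 50; must divide the
#'   per-chromosome length).
#' @param n_genes,n_enhancers Feature counts (defaults 200 and 1000).
#' @param n_activated Number of enhancers switching to the active state
#'   in condition B (default 100; must not exceed `n_enhancers`).
#' @param mark_effect_log2fc Mean log2 signal gain at activated
#'   enhancers in condition B, applied to both enhancer marks (default
#'   1.5).
#' @param expr_log2fc Mean log2 expression gain of genes nearest
#'   activated enhancers (default 2).
#' @param background_rate Background read rate per bin (default 2).
#' @param peak_enrichment Fold enrichment over background inside
#'   enhancer/TSS footprints (default 8).
#' @param noise_sd Per-(feature, mark, condition) biological noise on
#'   the log2 enrichment (default 0.25).
#' @param rna_dispersion Negative-binomial dispersion of RNA-seq counts
#'   (default 0.1; 0 gives Poisson).
#' @param rna_meanlog,rna_sdlog Log-normal parameters of baseline gene
#'   expression means (defaults `log(100)` and 0.5).
#' @param libsize_factor_a,libsize_factor_b Relative sequencing depth of
#'   the two RNA-seq libraries (defaults 1, 1).
#' @param enhancer_width Enhancer footprint width in bp (default 2000).
#' @param tss_footprint H3K4me3 promoter footprint width in bp (default
#'   1000).
#' @param gene_length_range Range of gene-body lengths in bp.
#' @param state_probs Condition-A state probabilities, named
#'   `active`/`primed`/`poised`/`inactive`.
#' @param seed Integer seed; identical configurations give bit-identical
#'   scenarios.
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(genome_length = 1e7, n_chromosomes = 1,
                            bin_size = 50, n_genes = 200,
                            n_enhancers = 1000, n_activated = 100,
                            mark_effect_log2fc = 1.5, expr_log2fc = 2,
                            background_rate = 2, peak_enrichment = 8,
                            noise_sd = 0.25, rna_dispersion = 0.1,
                            rna_meanlog = log(100), rna_sdlog = 0.5,
                            libsize_factor_a = 1, libsize_factor_b = 1,
                            enhancer_width = 2000, tss_footprint = 1000,
                            gene_length_range = c(2000, 10000),
                            state_probs = c(active = 0.40, primed = 0.35,
                                            poised = 0.10, inactive = 0.15),
                            seed = 1) {
  cfg <- list(genome_length = genome_length, n_chromosomes = n_chromosomes,
              bin_size = bin_size, n_genes = n_genes,
              n_enhancers = n_enhancers, n_activated = n_activated,
              mark_effect_log2fc = mark_effect_log2fc,
              expr_log2fc = expr_log2fc, background_rate = background_rate,
              peak_enrichment = peak_enrichment, noise_sd = noise_sd,
              rna_dispersion = rna_dispersion, rna_meanlog = rna_meanlog,
              rna_sdlog = rna_sdlog, libsize_factor_a = libsize_factor_a,
              libsize_factor_b = libsize_factor_b,
              enhancer_width = enhancer_width,
              tss_footprint = tss_footprint,
              gene_length_range = gene_length_range,
              state_probs = state_probs, seed = seed)
  validate_scenario_config(cfg)
}

validate_scenario_config <- function(cfg) {
  stopifnot_scalar_number(cfg$genome_length, "genome_length", 0, TRUE)
  stopifnot_scalar_number(cfg$bin_size, "bin_size", 0, TRUE)
  stopifnot_scalar_number(cfg$background_rate, "background_rate", 0, TRUE)
  stopifnot_scalar_number(cfg$peak_enrichment, "peak_enrichment", 0, TRUE)
  stopifnot_scalar_number(cfg$noise_sd, "noise_sd", 0)
  stopifnot_scalar_number(cfg$rna_dispersion, "rna_dispersion", 0)
  if (cfg$n_activated > cfg$n_enhancers)
    stop("n_activated must be <= n_enhancers", call. = FALSE)
  chrom_len <- cfg$genome_length / cfg$n_chromosomes
  if (chrom_len != floor(chrom_len))
    stop("genome_length must be divisible by n_chromosomes", call. = FALSE)
  if (chrom_len %% cfg$bin_size != 0)
    stop("bin_size must divide the per-chromosome length", call. = FALSE)
  nm <- names(cfg$state_probs)
  if (!setequal(nm, c("active", "primed", "poised", "inactive")))
    stop("state_probs must name active/primed/poised/inactive",
         call. = FALSE)
  cfg$state_probs <- cfg$state_probs / sum(cfg$state_probs)
  structure(cfg, class = "scenario_config")
}

# feature spacing that guarantees planted enhancers stay distinct after
# peak merging (> 500 bp apart) and clear of TSS-exclusion zones
.min_feature_gap <- 2500

#' Generate a synthetic genome with planted enhancer states
#'
#' Places non-overlapping gene bodies and intergenic enhancer footprints
#' (uniformly at random given the spacing constraints), assigns each
#' enhancer a condition-A chromatin state, plants the activated set
#' (primed/inactive in A, active in B), and links every enhancer to its
#' nearest-TSS gene to define the planted expression effects.
#'
#' @param config A `scenario_config`.
#' @return A `scenario` list: `genes` (gene models), `enhancers`
#'   (interval data.frame, names `enh_*`), `chrom_lengths`, `config` and
#'   `truth` (states per condition, `activated_set`, `gene_links`,
#'   `true_expr_fc`).
#' @export
make_genome <- function(config) {
  config <- validate_scenario_config(config)
  chrom_len <- config$genome_length / config$n_chromosomes
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  local_seed(config$seed, {
    ## feature -> chromosome assignment
    n_feat <- config$n_genes + config$n_enhancers
    is_gene <- c(rep(TRUE, config$n_genes), rep(FALSE, config$n_enhancers))
    feat_chrom <- sample(rep_len(chroms, n_feat))
    lens <- ifelse(is_gene,
                   round(runif(n_feat, config$gene_length_range[1],
                               config$gene_length_range[2])),
                   config$enhancer_width)
    starts <- numeric(n_feat)
    for (ch in chroms) {
      idx <- which(feat_chrom == ch)
      idx <- idx[sample.int(length(idx))]    # interleave genes/enhancers
      free <- chrom_len - sum(lens[idx]) -
        (length(idx) + 1) * .min_feature_gap
      if (free < 0)
        stop("infeasible packing: too many genes/enhancers for ",
             "genome_length (short by ", -free, " bp on ", ch, ")",
             call. = FALSE)
      if (length(idx)) {
        slack <- sort(runif(length(idx), 0, free))
        offs <- cumsum(c(.min_feature_gap,
                         lens[idx[-length(idx)]] + .min_feature_gap))
        starts[idx] <- floor(slack + offs)
      }
    }
    gi <- which(is_gene)
    ei <- which(!is_gene)
    genes <- gene_models(
      gene_id = sprintf("gene_%04d", seq_along(gi)),
      chrom = feat_chrom[gi], start = starts[gi],
      end = starts[gi] + lens[gi],
      strand = sample(c("+", "-"), length(gi), replace = TRUE))
    o <- order(genes$chrom, genes$start)
    genes <- genes[o, , drop = FALSE]
    rownames(genes) <- NULL
    enh <- genomic_intervals(
      chrom = feat_chrom[ei], start = starts[ei],
      end = starts[ei] + lens[ei],
      name = sprintf("enh_%04d", seq_along(ei)))
    enh <- enh[order(enh$chrom, enh$start), , drop = FALSE]
    enh$name <- sprintf("enh_%04d", seq_len(nrow(enh)))
    rownames(enh) <- NULL

    ## condition-A states; activated set drawn from primed/inactive
    states <- names(config$state_probs)
    states_a <- if (nrow(enh)) {
      sample(states, nrow(enh), replace = TRUE, prob = config$state_probs)
    } else character(0)
    eligible <- which(states_a %in% c("primed", "inactive"))
    if (length(eligible) < config$n_activated)
      stop("not enough primed/inactive enhancers (", length(eligible),
           ") to plant ", config$n_activated, " activations; increase ",
           "n_enhancers or primed/inactive state probabilities",
           call. = FALSE)
    activated <- sort(sample(eligible, config$n_activated))
    states_b <- states_a
    states_b[activated] <- "active"
    names(states_a) <- names(states_b) <- enh$name

    gene_links <- if (nrow(enh)) nearest_gene(enh, genes) else
      data.frame(enhancer_id = character(), gene_id = character(),
                 distance = numeric(), stringsAsFactors = FALSE)
    true_fc <- setNames(rep(1, nrow(genes)), genes$gene_id)
    act_genes <- gene_links$gene_id[gene_links$enhancer_id %in%
                                      enh$name[activated]]
    true_fc[unique(act_genes)] <- 2^config$expr_log2fc

    chrom_lengths <- setNames(rep(chrom_len, length(chroms)), chroms)
    structure(list(genes = genes, enhancers = enh,
                   chrom_lengths = chrom_lengths, config = config,
                   truth = list(states_a = states_a, states_b = states_b,
                                activated_set = enh$name[activated],
                                gene_links = gene_links,
                                true_expr_fc = true_fc)),
              class = "scenario")
  })
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("synthetic scenario: %s bp / %d chromosome(s)\n",
              format(x$config$genome_length, big.mark = ","),
              x$config$n_chromosomes))
  cat(sprintf("  %d genes, %d enhancers (%d activated in condition B)\n",
              nrow(x$genes), nrow(x$enhancers),
              length(x$truth$activated_set)))
  invisible(x)
}

# state -> marks carried at the enhancer footprint
.state_has_mark <- function(state, mark) {
  switch(mark,
         H3K4me1 = state %in% c("active", "primed", "poised"),
         H3K27ac = state == "active",
         stop("unknown enhancer mark: ", mark, call. = FALSE))
}

#' Simulate histone-mark coverage tracks
#'
#' Draws Poisson bin counts for each (mark, condition) with mean
#' `background_rate` outside footprints. Enhancer footprints carrying a
#' mark in their current state are enriched `peak_enrichment`-fold
#' (H3K4me1 at active/primed/poised enhancers, H3K27ac at active ones),
#' activated enhancers gain a further `2^mark_effect_log2fc` in
#' condition B, and H3K4me3 marks TSS footprints only. Per-(feature,
#' mark, condition) log-normal noise of sd `noise_sd` (log2 units)
#' models biological variability.
#'
#' @param scenario A `scenario` from [make_genome()].
#' @param marks Marks to simulate.
#' @return Nested list `tracks[[mark]][[condition]]` of raw-count
#'   `coverage_track` objects.
#' @export
simulate_mark_tracks <- function(scenario,
                                 marks = c("H3K4me1", "H3K27ac", "H3K4me3")) {
  stopifnot(inherits(scenario, "scenario"))
  cfg <- scenario$config
  bad <- setdiff(marks, c("H3K4me1", "H3K27ac", "H3K4me3"))
  if (length(bad))
    stop("unknown mark(s): ", paste(bad, collapse = ", "), call. = FALSE)
  bs <- cfg$bin_size
  n_bins <- scenario$chrom_lengths / bs
  enh <- scenario$enhancers
  genes <- scenario$genes
  local_seed(cfg$seed + 1L, {
    out <- list()
    for (m in marks) {
      out[[m]] <- list()
      for (cond in c("A", "B")) {
        mult <- lapply(n_bins, function(n) rep(1, n))
        if (m %in% c("H3K4me1", "H3K27ac")) {
          states <- if (cond == "A") scenario$truth$states_a else
            scenario$truth$states_b
          has <- .state_has_mark(states[enh$name], m)
          noise <- 2^rnorm(nrow(enh), 0, cfg$noise_sd)
          boost <- ifelse(cond == "B" &
                            enh$name %in% scenario$truth$activated_set,
                          2^cfg$mark_effect_log2fc, 1)
          for (i in which(has)) {
            ch <- enh$chrom[i]
            i0 <- floor(enh$start[i] / bs) + 1
            i1 <- ceiling(enh$end[i] / bs)
            mult[[ch]][i0:i1] <- cfg$peak_enrichment * noise[i] * boost[i]
          }
        } else {
          half <- cfg$tss_footprint / 2
          noise <- 2^rnorm(nrow(genes), 0, cfg$noise_sd)
          for (i in seq_len(nrow(genes))) {
            ch <- genes$chrom[i]
            i0 <- max(1, floor((genes$tss[i] - half) / bs) + 1)
            i1 <- min(n_bins[[ch]], ceiling((genes$tss[i] + half) / bs))
            mult[[ch]][i0:i1] <- cfg$peak_enrichment * noise[i]
          }
        }
        bins <- lapply(names(mult), function(ch)
          rpois(length(mult[[ch]]), cfg$background_rate * mult[[ch]]))
        names(bins) <- names(mult)
        out[[m]][[cond]] <- coverage_track(bins, bs,
                                           scenario$chrom_lengths,
                                           units = "raw")
      }
    }
    out
  })
}

#' Simulate an RNA-seq gene-count table
#'
#' Baseline per-gene means are log-normal; condition-B means multiply in
#' the planted fold changes (`2^expr_log2fc` for genes nearest activated
#' enhancers). Counts are negative binomial with dispersion
#' `rna_dispersion` (Poisson when 0); library-size factors scale the two
#' conditions.
#'
#' @param scenario A `scenario` from [make_genome()].
#' @return data.frame with columns `gene_id`, `count_A`, `count_B`.
#' @export
simulate_rnaseq <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  cfg <- scenario$config
  genes <- scenario$genes
  local_seed(cfg$seed + 2L, {
    base <- rlnorm(nrow(genes), cfg$rna_meanlog, cfg$rna_sdlog)
    fc <- scenario$truth$true_expr_fc[genes$gene_id]
    mu_a <- base * cfg$libsize_factor_a
    mu_b <- base * fc * cfg$libsize_factor_b
    draw <- function(mu) {
      if (cfg$rna_dispersion > 0)
        rnbinom(length(mu), mu = mu, size = 1 / cfg$rna_dispersion)
      else rpois(length(mu), mu)
    }
    data.frame(gene_id = genes$gene_id,
               count_A = draw(mu_a), count_B = draw(mu_b),
               stringsAsFactors = FALSE)
  })
}

#' Write a scenario's inputs to disk
#'
#' Emits the file set a real analysis would start from: one bedGraph per
#' (mark, condition), a BED6 of gene bodies, a TSV annotation, a TSV
#' gene-count table and a JSON ground-truth file.
#'
#' @param scenario A `scenario`.
#' @param dir Output directory (created if needed).
#' @param tracks,counts Optional pre-simulated tracks/counts (simulated
#'   from the scenario when omitted).
#' @return Named list of written paths, invisibly.
#' @export
write_scenario <- function(scenario, dir, tracks = NULL, counts = NULL) {
  stopifnot(inherits(scenario, "scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(tracks)) tracks <- simulate_mark_tracks(scenario)
  if (is.null(counts)) counts <- simulate_rnaseq(scenario)
  paths <- list()
  for (m in names(tracks)) for (cond in names(tracks[[m]])) {
    p <- file.path(dir, sprintf("%s_%s.bedGraph", m, cond))
    write_bedgraph(tracks[[m]][[cond]], p)
    paths[[sprintf("%s_%s", m, cond)]] <- p
  }
  g <- scenario$genes
  paths$genes_bed <- write_bed(
    genomic_intervals(g$chrom, g$start, g$end, name = g$gene_id,
                      strand = g$strand),
    file.path(dir, "genes.bed"))
  paths$annotation <- write_annotation(g, file.path(dir, "genes.tsv"))
  paths$counts <- file.path(dir, "gene_counts.tsv")
  write.table(counts, paths$counts, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(states_a = as.list(scenario$truth$states_a),
         states_b = as.list(scenario$truth$states_b),
         activated_set = scenario$truth$activated_set,
         gene_links = scenario$truth$gene_links,
         true_expr_fc = as.list(scenario$truth$true_expr_fc)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
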