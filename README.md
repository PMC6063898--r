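# deltamark

Differential enhancer-activation analysis from two-condition
histone-mark ChIP-seq, with the accompanying bench-assay calculators
and a synthetic-data generator for end-to-end validation.

## The problem

When a tumour (or any cell population) changes phenotype between two
conditions — for example a drug-sensitive line A and a resistant
derivative B — part of the change is often driven by *enhancers* that
switch chromatin state rather than by mutations. Enhancer state is read
out from histone marks: H3K4me1 marks primed and active enhancers,
H3K27ac distinguishes active ones, H3K4me3 flags promoters. An enhancer
that gains both H3K4me1 and H3K27ac in condition B has been
*activated*, and the gene nearest its position is the prime candidate
target — up to and including a drug-resistance gene sitting hundreds of
kilobases away.

`deltamark` turns that reasoning into a tested pipeline:

1. **Catalog.** Call enriched regions on binned coverage with a
   local-Poisson test (per-bin p-value against
   `lambda = max(global mean, local 10 kb mean)`, cutoff `p < 0.001`),
   take the union of H3K4me1 peaks from both conditions, drop regions
   overlapping H3K4me3 peaks or within 2 kb of a TSS, and merge
   neighbours closer than 500 bp.
2. **State ratios.** For each catalog enhancer and each mark compute
   `log2((RPKM_B + c) / (RPKM_A + c))` with pseudocount `c = 0.5`.
3. **Clustering.** k-means (k-means++ seeding, 10 restarts, fixed
   seed, default `k = 4`) on the two-column ratio matrix; the
   *activated group* is the union of clusters whose centroids are
   positive in both marks.
4. **Gene linkage.** Each enhancer is linked to the gene with the
   nearest TSS; per-gene expression fold changes are
   `(count_B/N_B) / (count_A/N_A)` with an exact conditional-binomial
   p-value and Benjamini–Hochberg adjustment; the activated group's
   genes are ranked by fold change.

The quantification formulas for the follow-up bench assays are included
as pure calculators: 3C interaction frequency `2^(Ct_BAC − Ct_3C)`,
ChIP-qPCR percent input, dual-luciferase double normalization, ΔΔCt
fold change, immunofluorescence nuclear signal (area × mean intensity)
with positive-fraction gating, four-parameter logistic IC50 fitting,
and per-day proliferation rates.

Because every computational claim needs ground truth, the package ships
a first-class synthetic-data generator: genomes with non-overlapping
genes and intergenic enhancers, per-condition chromatin states with a
planted activated subset, Poisson mark tracks, negative-binomial
RNA-seq counts whose fold changes are coupled to enhancer activation,
and assay tables generated by inverting each calculator's formula.

## Worked example

```r
library(deltamark)

cfg      <- scenario_config(genome_length = 2e6, n_genes = 60,
                            n_enhancers = 150, n_activated = 20, seed = 42)
scenario <- make_genome(cfg)
tracks   <- simulate_mark_tracks(scenario)
counts   <- simulate_rnaseq(scenario)

peaks <- lapply(tracks[c("H3K4me1", "H3K4me3")],
                function(t) lapply(t, call_peaks, p_cutoff = 0.001))
putative <- select_putative_enhancers(
  peaks$H3K4me1$A, peaks$H3K4me1$B,
  merge_close_peaks(rbind(peaks$H3K4me3$A[, 1:6],
                          peaks$H3K4me3$B[, 1:6]), 0),
  scenario$genes)
catalog <- attach_signal(merge_close_peaks(putative, max_gap = 500),
                         lapply(tracks[c("H3K4me1", "H3K27ac")],
                                function(t) lapply(t, rpkm_normalize)))
fit <- enhancer_activation(catalog, scenario$genes,
                           setNames(counts$count_A, counts$gene_id),
                           setNames(counts$count_B, counts$gene_id),
                           k = 4, seed = 42)
fit
```

```
Differential enhancer-activation analysis
  139 enhancers clustered (k = 4); activated group: 20
  top activated-group genes by fold change:
 rank   gene_id fold_change  p_value adjusted_p
    1 gene_0012       7.054 1.32e-39   3.96e-38
    2 gene_0057       6.554 4.07e-50   2.44e-48
    3 gene_0003       3.988 2.06e-26   1.77e-25
    4 gene_0043       3.388 2.57e-36   3.85e-35
    5 gene_0059       2.841 3.51e-31   4.22e-30
```

All 20 planted activated enhancers land in the activated group (139
catalog enhancers clustered, 20 selected), and the ranked table's top
genes are those nearest the planted activations — fold changes of 3–7×
around the planted 4× effect, with the binomial p-values and their BH
adjustments in the last two columns. `summary(fit)` shows the four
cluster centroids (here the two activated sub-populations at
`(1.2, 4.1)` and `(4.2, 3.9)` log2 gain, and two null clusters near the
origin); `plot(fit)` draws the ratio scatter coloured by cluster.

The same analysis runs end to end, with all artifacts written to disk
(catalog BED, ratio matrix TSV, activated-group BED, ranked gene table,
metaprofiles, JSON manifest), via:

```r
fit <- run_pipeline(list(scenario = TRUE, seed = 1), "results_dir")
```

or from the shell through `inst/scripts/deltamark-pipeline.R`. Real
data enters the same way: bedGraph tracks per (mark, condition), a TSV
gene annotation and a TSV count table, named in the config instead of
`scenario = TRUE`.

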