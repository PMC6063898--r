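---
title: "deltamark: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{deltamark: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical model behind `deltamark`, the
parameters that matter, the synthetic-data generator used for
validation, and the design decisions that were genuinely open — with
the reasoning behind each.

## The analysis model

### Coverage and normalization

All signal lives in fixed-width bins (default 50 bp). Reads are
assigned to bins by their 5′ position; nothing else about a read is
used. Between-sample comparability is by RPKM,
`count / (bin_size/1000) / (total_mapped/1e6)`, a linear and (given the
library size) invertible transform. RPKM corrects sequencing depth but
not composition: if condition B gains a large amount of signal at
activated enhancers, the RPKM of *unchanged* regions drifts slightly
downward in B. We keep this behaviour deliberately — it is exactly what
happens in real depth-normalized ChIP-seq without spike-in controls,
and the clustering step absorbs the small global shift into the null
clusters. Spike-in normalization is out of scope.

### Peak calling

The caller is intentionally minimal: each bin's count is tested against
an upper-tail Poisson null with
`lambda = max(genome-wide mean, local mean over a 10 kb window)`, and
runs of adjacent significant bins (`p < 0.001`, the fixed cutoff used
throughout) become peaks. The local-maximum lambda mirrors the
local-background strategy of standard ChIP-seq callers at bin
resolution and makes the test conservative by construction: on null
(uniform Poisson) tracks the realized per-bin false-positive rate is
below the nominal cutoff, which the test suite verifies by simulation.
No multiple-testing correction is applied at this stage — the cutoff is
a fixed operating point, not an inference. p-values are computed on raw
counts; calling on normalized tracks is refused.

Peaks from a strong enhancer typically fragment (interior bins dip
below the threshold by Poisson chance), which is harmless because the
catalog construction merges fragments closer than 500 bp anyway.

### Enhancer catalog

Putative enhancers are distal H3K4me1-high / H3K4me3-low regions:

* union of H3K4me1 peaks from the two conditions (an enhancer primed or
  active in *either* condition belongs in the catalog — an enhancer
  gaining H3K4me1 only in B would otherwise be invisible). An
  intersection mode is available for stricter definitions;
* minus any region overlapping an H3K4me3 peak (promoter mark, either
  condition);
* minus any region within 2 kb of an annotated TSS (`tss_exclusion`,
  configurable) — "distal" made operational;
* neighbours with a gap strictly less than 500 bp merged, transitively.
  Overlapping or bookended intervals (gap ≤ 0) always merge, so the
  merge is idempotent and well defined for every `max_gap` including 0.

"High H3K4me1 / low H3K4me3" is operationalized as presence/absence of
called peaks rather than as signal thresholds: peak calls are the only
discretization with a stated operating point, and thresholds on
continuous signal would introduce two more free parameters.

### State ratios and clustering

For each catalog enhancer and each of the two enhancer marks the state
change is `log2((RPKM_B + c)/(RPKM_A + c))` with pseudocount
`c = 0.5` RPKM. The pseudocount keeps every entry finite and shrinks
ratios at low coverage toward 0; when both signals are exactly zero the
entry is defined as 0 rather than `log2(c/c)` being left to floating
point. Swapping the conditions negates the matrix exactly (a tested
invariant).

The two-column matrix is clustered by k-means with k-means++ seeding,
10 restarts and a fixed seed (Lloyd iterations via `stats::kmeans`).
Determinism matters more here than squeezing the last percent of
within-cluster variance: the same configuration and seed must give
byte-identical pipeline output. `k = 4` by default — enough to separate
"up in both marks", "down", and "unchanged" behaviours with one spare —
but the *selection* of the activated group does not depend on k being
right.

### Selecting the activated group

The activated group is the union of all clusters whose centroid is
positive in **both** ratio dimensions (threshold `min_gain`, default
0). A rule on centroids, not a cluster index, for two reasons. First,
cluster numbering is arbitrary. Second — and this is the reason the
rule takes a union rather than the single best cluster — activated
enhancers are not one population. An enhancer that was *primed* (marked
by H3K4me1 alone) and becomes active gains H3K27ac massively but
H3K4me1 only moderately; one that was fully *inactive* gains both marks
strongly. With `k = 4` these arrive as two distinct positive-both
clusters, and selecting only the strongest would silently discard the
primed-to-active majority. If no centroid is positive in both marks the
group is empty and a warning is raised rather than returning the least
negative cluster.

### Gene linkage and ranking

Each enhancer is linked to the gene minimizing the distance from the
enhancer midpoint to the TSS (same chromosome; ties broken by lower TSS
coordinate, then lexicographic gene id, so assignments are
deterministic and translation-invariant). TSS distance, not gene-body
distance, because promoters are where enhancer contacts act.

Expression fold change is the ratio of library-size-normalized counts
with a small pseudo-fraction (10⁻⁶ of the mean normalized count)
guarding division by zero. With one library per condition no dispersion
is estimable, so significance uses the exact conditional binomial: given
a gene's total count `n = a + b`, under the null
`b ~ Binomial(n, N_B/(N_A + N_B))`; two-sided p-values by the
minimum-likelihood rule (`stats::binom.test`), Benjamini–Hochberg
step-up for the adjusted column. This is the natural exact test for the
single-replicate design; it is calibrated (conservatively, counts being
discrete) under the null, which the suite checks by simulation. The
ranked table reports genes linked to activated-group enhancers, sorted
by fold change descending, deduplicated by keeping the closest linking
enhancer, both linear and log2 fold changes emitted.

## The synthetic-data generator

The generator is first-class, tested code: every downstream claim about
recovery is made against its planted truth.

* **Genome.** Genes and 2 kb enhancer footprints are placed uniformly
  at random in a fixed-length genome with a minimum spacing of 2.5 kb
  between any two features (a spacings construction — sorted uniforms
  plus cumulative feature lengths — so placement needs no rejection
  loop and an infeasible request fails with a sizing error). The
  spacing guarantees planted enhancers stay distinct through the 500 bp
  merge and clear of the 2 kb TSS exclusion, so catalog intervals map
  one-to-one onto planted enhancers by overlap. No positional
  structure beyond non-overlap is modelled.
* **States.** Each enhancer gets a condition-A state (active 40%,
  primed 35%, poised 10%, inactive 15%); the activated set is drawn
  from the primed/inactive pool and switched to active in condition B.
* **Marks.** Poisson bin counts. Background rate 2 reads/bin;
  footprints carrying a mark in the current state are enriched 8-fold;
  activated enhancers gain a further `2^1.5` in condition B
  (`mark_effect_log2fc = 1.5`); per-(feature, mark, condition)
  log-normal noise of 0.25 log2 units models biological variability.
  H3K4me1 is present at active, primed and poised enhancers, H3K27ac
  only at active ones, H3K4me3 only in 1 kb TSS footprints. The
  H3K27me3/H3K9me3 axis of the poised state is not simulated — the
  clustered matrix uses only the two enhancer marks.
* **RNA-seq.** Negative binomial (dispersion 0.1) around log-normal
  baseline means (log-mean `log(100)`, log-sd 0.5); genes nearest
  activated enhancers get mean fold change `2^expr_log2fc` (default 4×)
  in condition B; per-condition library-size factors are configurable
  for normalization tests.
* **Assays.** Each table is generated by inverting the corresponding
  calculator: Ct values as `−log2(template) + intercept + noise`,
  dose-response points from the 4PL with planted IC50, per-nucleus
  signals from a two-component mixture with a planted positive
  fraction. At zero noise every calculator inverts its generator
  exactly, which the suite asserts.

The default scenario is desk-scale: one 10 Mb chromosome, 50 bp bins,
200 genes, 1,000 enhancers, 100 activated. Enrichment and noise
magnitudes are not estimated from any dataset — real tracks come with
no stated effect sizes — so they were chosen once for detectability at
this scale and are stated in `scenario_config()` rather than hidden.
What passing tests show, therefore, is that the pipeline's logic
recovers planted truth under its own model assumptions (Poisson
counts, clean states, one-to-one enhancer–gene links). They do not show
robustness to mappability artifacts, copy-number changes, fragment-size
effects, overlapping enhancer clusters or many-to-many enhancer–gene
regulation, none of which the generator emulates.

## Assay calculators

All qPCR formulas assume perfect primer efficiency (doubling per
cycle); no efficiency correction is applied anywhere. The 3C
interaction frequency is `2^(Ct_BAC − Ct_3C)` on replicate means, with
the standard error reported both with and without propagating the BAC
control's replicate variance (delta method on the log2 scale) — the
control's contribution is small but there is no principled reason to
hide it, so both variants are returned. Machine-offset invariance
(adding a constant to all Cts) holds for the 3C and ΔΔCt formulas;
scale invariance in instrument units holds for the dual-luciferase
ratio; both are tested identities.

The immunofluorescence positivity rule is qualitative at the bench
("uniform staining"), so the calculator makes it explicit: a nucleus is
positive when `area × mean intensity` exceeds a threshold, either fixed
or `3 × median` of a negative-control set, and gating
(e.g. Ki67-positive, CD45-negative for proliferating tumour cells) is
applied with the same rule per channel.

### Dose-response fitting

The 4PL `bottom + (top − bottom)/(1 + (dose/IC50)^hill)` is fitted by
Levenberg–Marquardt least squares with range/half-crossing starting
values; the reported IC50 is the relative (inflection) IC50. Flat
responses are refused — an unidentifiable fit raises an error rather
than returning a silent number. For viability already normalized to an
untreated control the standard analysis constrains `top = 1` and
`bottom = 0` ("normalized response, variable slope"), exposed as
`fix_top`/`fix_bottom`. The constraint matters quantitatively: with 8
doses × 3 replicates at 5% multiplicative noise, the fully free
four-parameter fit leaves the IC50 with a sampling error whose 95th
percentile exceeds 10% regardless of estimator (the information in the
design is the limit, not the optimizer), while the constrained fit
recovers the IC50 within 10% in ≥95% of simulations — the recovery
property the test suite asserts.

## Numerical and engineering choices

* Coordinates are 0-based half-open (BED convention) everywhere
  internally; rtracklayer handles on-disk conversion. bedGraph (text,
  diff-able) is the canonical track format.
* Partial bins in `mean_signal` are weighted by covered bases, making
  the mean exactly the per-base average of the piecewise-constant
  signal (checked against a brute-force per-base oracle).
* Degenerate inputs have defined behaviour rather than crashes: ratio
  entries at 0/0 coverage are 0; k-means on fewer distinct rows than k
  assigns one cluster per distinct row; catalog intervals outside track
  bounds are flagged and excluded with a warning; an empty activated
  group warns.
* All simulation functions restore the caller's RNG state; every
  stochastic step is seeded through configuration, and the end-to-end
  pipeline is byte-identical across reruns of the same config and seed
  (tested via file checksums). The run manifest records the
  configuration, seed, package version and stage counts — everything
  needed to reproduce an output, and nothing (like timestamps) that
  would break reproducibility.

## Problem sizes

The validation suite runs at deliberately modest scale: the default
10 Mb scenario for activated-group recovery (10 seeds), 1,000 random
interval sets for the merge oracle, 500 × 100 for the nearest-gene
oracle, 100 replicates for the ranked-table, IC50 and peak-calibration
experiments, 50 for RNA-seq fold-change recovery. These sizes give the
Monte-Carlo properties being asserted comfortable margins while keeping
the whole suite runnable on a laptop in a few minutes.

## Known limitations

* Peak calling has no input/control track and no fragment-shift model;
  users with MACS2 output can supply their peak BEDs directly and skip
  the internal caller.
* Nearest-TSS linkage is a heuristic; it ignores TADs, contact maps and
  many-to-many regulation.
* RPKM without spike-ins cannot distinguish a global gain from
  composition drift (discussed above).
* The exact binomial DE test treats the two libraries as fixed sums; it
  has no biological-variance term and its p-values should be read as
  single-replicate screening statistics, as in the ranked table, not as
  population-level inference.
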