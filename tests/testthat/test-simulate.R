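test_that("scenario configuration validates its invariants", {
  expect_s3_class(scenario_config(), "scenario_config")
  expect_error(scenario_config(n_activated = 2000), "n_activated")
  expect_error(scenario_config(bin_size = 33), "divide")
  expect_error(scenario_config(background_rate = 0), "> 0")
  expect_error(scenario_config(genome_length = 1e7, n_chromosomes = 3),
               "divisible")
})

test_that("genome generation is deterministic and respects packing", {
  cfg <- do.call(scenario_config, small_scenario_args(seed = 1))
  s1 <- make_genome(cfg)
  s2 <- make_genome(cfg)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$enhancers, s2$enhancers)
  expect_identical(s1$truth, s2$truth)

  # no enhancers: valid gene annotation, empty enhancer set
  s0 <- make_genome(scenario_config(genome_length = 1e6, n_genes = 20,
                                    n_enhancers = 0, n_activated = 0))
  expect_equal(nrow(s0$enhancers), 0L)
  expect_equal(nrow(s0$genes), 20L)

  # infeasible packing raises a sizing error
  expect_error(make_genome(scenario_config(genome_length = 1e6,
                                           n_genes = 50,
                                           n_enhancers = 500,
                                           n_activated = 10)),
               "infeasible packing")
})

test_that("gene bodies never overlap (brute-force pairwise scan)", {
  s <- make_genome(scenario_config(genome_length = 5e6, n_genes = 50,
                                   n_enhancers = 100, n_activated = 10,
                                   seed = 3))
  g <- s$genes
  for (i in seq_len(nrow(g) - 1)) {
    for (j in (i + 1):nrow(g)) {
      same <- g$chrom[i] == g$chrom[j]
      overlap <- g$start[i] < g$end[j] && g$start[j] < g$end[i]
      expect_false(same && overlap)
    }
  }
  # enhancers sit in intergenic space
  expect_false(any(deltamark:::overlaps_any(s$enhancers, s$genes)))
})

test_that("ground truth couples states, activation and expression", {
  s <- make_genome(do.call(scenario_config, small_scenario_args()))
  tr <- s$truth
  expect_true(all(tr$activated_set %in% s$enhancers$name))
  expect_true(all(tr$states_b[tr$activated_set] == "active"))
  expect_true(all(tr$states_a[tr$activated_set] %in%
                    c("primed", "inactive")))
  # every planted expression effect traces back to an activated enhancer
  up <- names(tr$true_expr_fc)[tr$true_expr_fc > 1]
  src <- tr$gene_links$gene_id[tr$gene_links$enhancer_id %in%
                                 tr$activated_set]
  expect_setequal(up, unique(src))
})

test_that("mark tracks carry state-dependent enrichment", {
  args <- small_scenario_args(seed = 2)
  s <- make_genome(do.call(scenario_config, args))
  # pick one enhancer that is primed in A and active in B
  cand <- with(s$truth, names(states_a)[states_a == "primed" &
                                          states_b == "active"])
  expect_gt(length(cand), 0)
  e <- s$enhancers[s$enhancers$name == cand[1], ]
  # H3K27ac over its bins is higher in B than A across replicate draws
  mean_sig <- function(seed, mark, cond) {
    s2 <- s; s2$config$seed <- seed
    tr <- simulate_mark_tracks(s2, marks = mark)[[mark]][[cond]]
    mean_signal(tr, e$chrom, e$start, e$end)
  }
  k27_a <- vapply(1:20, mean_sig, numeric(1), mark = "H3K27ac", cond = "A")
  k27_b <- vapply(1:20, mean_sig, numeric(1), mark = "H3K27ac", cond = "B")
  expect_gt(mean(k27_b), mean(k27_a))
  expect_gt(mean(k27_b), 5 * mean(k27_a))  # enrichment, not drift

  # determinism: same seed -> bit-identical tracks
  t1 <- simulate_mark_tracks(s)
  t2 <- simulate_mark_tracks(s)
  expect_identical(t1, t2)
  expect_error(simulate_mark_tracks(s, marks = "H3K9me3"), "unknown mark")
})

test_that("background regions match the configured rate", {
  s <- make_genome(scenario_config(genome_length = 1e6, n_genes = 5,
                                   n_enhancers = 5, n_activated = 0,
                                   background_rate = 2, seed = 4))
  tr <- simulate_mark_tracks(s, marks = "H3K27ac")$H3K27ac$A
  # mask out enhancer/TSS footprints, keep pure background bins
  bg <- rep(TRUE, length(tr$bins$chr1))
  for (i in seq_len(nrow(s$enhancers))) {
    i0 <- floor(s$enhancers$start[i] / 50) + 1
    i1 <- ceiling(s$enhancers$end[i] / 50)
    bg[i0:i1] <- FALSE
  }
  x <- tr$bins$chr1[bg]
  expect_gt(length(x), 1000)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 2), 3 * se)
  # conservation: total_mapped equals the sum over bins
  expect_equal(tr$total_mapped, sum(tr$bins$chr1))
})

test_that("null configuration leaves conditions indistinguishable at enhancers", {
  s <- make_genome(scenario_config(genome_length = 1e6, n_genes = 10,
                                   n_enhancers = 40, n_activated = 10,
                                   peak_enrichment = 1,
                                   mark_effect_log2fc = 0, noise_sd = 0,
                                   seed = 6))
  tr <- simulate_mark_tracks(s, marks = "H3K4me1")$H3K4me1
  sig_a <- deltamark:::interval_means(tr$A, s$enhancers)
  sig_b <- deltamark:::interval_means(tr$B, s$enhancers)
  expect_gt(t.test(sig_a, sig_b, paired = TRUE)$p.value, 0.001)
})

test_that("RNA-seq simulation recovers planted fold changes", {
  args <- list(genome_length = 2e6, n_genes = 60, n_enhancers = 60,
               n_activated = 1, expr_log2fc = 4, seed = 10)
  s <- make_genome(do.call(scenario_config, args))
  planted <- names(s$truth$true_expr_fc)[s$truth$true_expr_fc > 1]
  expect_length(planted, 1)
  est <- vapply(1:50, function(r) {
    s2 <- s; s2$config$seed <- 100 + r
    cnt <- simulate_rnaseq(s2)
    fc <- expression_fold_change(setNames(cnt$count_A, cnt$gene_id),
                                 setNames(cnt$count_B, cnt$gene_id))
    unname(fc[planted])
  }, numeric(1))
  expect_gt(mean(est), 12)
  expect_lt(mean(est), 20)

  # null effect: median fold change near 1
  s0 <- make_genome(scenario_config(genome_length = 2e6, n_genes = 60,
                                    n_enhancers = 60, n_activated = 0,
                                    seed = 11))
  cnt <- simulate_rnaseq(s0)
  fc0 <- expression_fold_change(setNames(cnt$count_A, cnt$gene_id),
                                setNames(cnt$count_B, cnt$gene_id))
  expect_lt(abs(log2(median(fc0))), 0.3)
})

test_that("library-size normalization removes depth bias from fold changes", {
  s <- make_genome(scenario_config(genome_length = 2e6, n_genes = 60,
                                   n_enhancers = 60, n_activated = 0,
                                   libsize_factor_b = 2, seed = 12))
  med <- vapply(1:20, function(r) {
    s2 <- s; s2$config$seed <- 200 + r
    cnt <- simulate_rnaseq(s2)
    a <- setNames(cnt$count_A, cnt$gene_id)
    b <- setNames(cnt$count_B, cnt$gene_id)
    c(naive = median(b / pmax(a, 1)),
      normalized = median(expression_fold_change(a, b)))
  }, numeric(2))
  expect_gt(mean(med["naive", ]), 1.7)        # 2x depth shows up raw
  expect_lt(abs(log2(mean(med["normalized", ]))), 0.15)
})

test_that("scenario files round-trip through the writers", {
  s <- make_genome(scenario_config(genome_length = 2e5, n_genes = 5,
                                   n_enhancers = 10, n_activated = 2,
                                   seed = 13))
  dir <- withr::local_tempdir()
  paths <- write_scenario(s, dir)
  expect_true(all(file.exists(unlist(paths))))
  genes <- read_annotation(paths$annotation)
  expect_equal(genes, s$genes, ignore_attr = TRUE)
  tr <- read_bedgraph(paths$H3K4me1_A, bin_size = 50,
                      chrom_lengths = s$chrom_lengths)
  expect_equal(sum(tr$bins$chr1) > 0, TRUE)
  truth <- jsonlite::read_json(paths$truth)
  expect_equal(unlist(truth$activated_set), s$truth$activated_set)
})
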