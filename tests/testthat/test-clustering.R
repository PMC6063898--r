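make_catalog <- function(sig_a1, sig_b1, sig_a2, sig_b2) {
  iv <- genomic_intervals("chr1", seq(0, by = 1000,
                                      length.out = length(sig_a1)),
                          seq(500, by = 1000,
                              length.out = length(sig_a1)))
  iv$name <- sprintf("e%03d", seq_along(sig_a1))
  iv$signal_H3K4me1_A <- sig_a1
  iv$signal_H3K4me1_B <- sig_b1
  iv$signal_H3K27ac_A <- sig_a2
  iv$signal_H3K27ac_B <- sig_b2
  structure(iv, class = c("enhancer_catalog", "data.frame"))
}

test_that("ratio matrix follows the pseudocounted log2 formula", {
  cat1 <- make_catalog(c(5, 2, 0), c(5, 4, 0), c(1, 3, 0), c(1, 6, 0))
  m <- compute_ratio_matrix(cat1, pseudocount = 0.5)
  expect_equal(dim(m), c(3L, 2L))
  # equal signals -> 0 for any pseudocount
  expect_equal(m[1, ], c(log2_ratio_H3K4me1 = 0, log2_ratio_H3K27ac = 0))
  # doubling -> 1 as pseudocount -> 0
  m0 <- compute_ratio_matrix(cat1, pseudocount = 1e-12)
  expect_equal(unname(m0[2, ]), c(1, 1), tolerance = 1e-9)
  # both zero -> exactly 0
  expect_equal(unname(m[3, ]), c(0, 0))
  expect_error(compute_ratio_matrix(cat1, condition_b = "C"), "lacks")
})

test_that("swapping conditions negates every ratio entry", {
  set.seed(31)
  cat1 <- make_catalog(runif(50, 0, 10), runif(50, 0, 10),
                       runif(50, 0, 10), runif(50, 0, 10))
  m_ab <- compute_ratio_matrix(cat1, "A", "B")
  m_ba <- compute_ratio_matrix(cat1, "B", "A")
  expect_equal(m_ba, -m_ab)
})

test_that("k-means recovers well-separated planted blobs exactly", {
  set.seed(17)
  truth <- rep(1:2, each = 100)
  mat <- rbind(matrix(rnorm(200, -1, 0.2), ncol = 2),
               matrix(rnorm(200, 1.5, 0.2), ncol = 2))
  rownames(mat) <- sprintf("e%03d", 1:200)
  cl <- kmeans_cluster(mat, k = 2, seed = 5)
  expect_equal(adjusted_rand_index(cl$labels, truth), 1.0)
  # determinism under a fixed seed
  cl2 <- kmeans_cluster(mat, k = 2, seed = 5)
  expect_identical(cl$labels, cl2$labels)
  expect_error(kmeans_cluster(mat[1:3, ], k = 4), "fewer rows")
  expect_error(kmeans_cluster(mat, k = 1), ">= 2")
})

test_that("identical rows collapse into one populated cluster without crashing", {
  mat <- matrix(1, nrow = 10, ncol = 2,
                dimnames = list(sprintf("e%02d", 1:10), NULL))
  cl <- kmeans_cluster(mat, k = 4, seed = 1)
  expect_equal(unname(cl$labels), rep(1L, 10))
  expect_true(all(is.na(cl$centroids[2:4, ])))
})

test_that("activated-group selection follows the positive-both-centroid rule", {
  labels <- setNames(c(1, 1, 2, 3, 3), sprintf("e%d", 1:5))
  cents <- rbind(c(0.8, 0.9), c(-0.5, -0.4), c(0.1, -0.2))
  expect_equal(select_activated_group(labels, cents), c("e1", "e2"))
  # no positive-both centroid: empty with warning
  cents2 <- rbind(c(-0.8, 0.9), c(-0.5, -0.4), c(0.1, -0.2))
  expect_warning(got <- select_activated_group(labels, cents2),
                 "empty activated group")
  expect_length(got, 0)
  # several positive-both centroids: union of their clusters
  cents3 <- rbind(c(0.8, 0.9), c(1.5, 4), c(0.1, -0.2))
  expect_equal(select_activated_group(labels, cents3),
               c("e1", "e2", "e3"))
  # NA centroids (empty clusters) are never selected
  cents4 <- rbind(c(0.8, 0.9), c(NA, NA), c(0.1, -0.2))
  expect_equal(select_activated_group(labels, cents4), c("e1", "e2"))
})

test_that("metaprofiles are flat on constant tracks in every mode", {
  tr <- constant_track(2.5, n_bins = 2000, bin_size = 50)
  iv <- genomic_intervals("chr1", c(20000, 40000), c(22000, 42000))
  genes <- gene_models(c("g1", "g2"), "chr1", c(30000, 60000),
                       c(35000, 70000), c("+", "-"))
  for (mode in c("center", "tss", "scaled")) {
    anch <- if (mode == "center") iv else genes
    mp <- metaprofile(tr, anch, mode = mode, window = 5000)
    expect_true(all(mp$mean_signal == 2.5), info = mode)
  }
})

test_that("single-anchor center profile equals the local window values", {
  set.seed(23)
  tr <- coverage_track(list(chr1 = runif(1000, 0, 5)), 50)
  iv <- genomic_intervals("chr1", 20000, 22000)  # center 21000
  mp <- metaprofile(tr, iv, mode = "center", window = 1000)
  want <- tr$bins$chr1[floor((21000 + seq(-1000, 1000, 50)) / 50) + 1]
  expect_equal(mp$mean_signal, want)
})

test_that("TSS-anchored profile matches brute-force extraction and flipping", {
  set.seed(29)
  tr <- coverage_track(list(chr1 = runif(4000, 0, 5)), 50)
  genes <- gene_models(sprintf("g%d", 1:20), "chr1",
                       seq(10000, 180000, length.out = 20),
                       seq(10000, 180000, length.out = 20) + 5000,
                       sample(c("+", "-"), 20, TRUE))
  win <- 2000
  mp <- metaprofile(tr, genes, mode = "tss", window = win)
  offs <- seq(-win, win, by = 50)
  rows <- t(vapply(seq_len(nrow(genes)), function(i) {
    v <- tr$bins$chr1[floor((genes$tss[i] + offs) / 50) + 1]
    if (genes$strand[i] == "-") rev(v) else v
  }, numeric(length(offs))))
  expect_equal(mp$mean_signal, colMeans(rows), tolerance = 1e-9)
  expect_equal(attr(mp, "n_anchors"), 20L)
})

test_that("metaprofiles are linear in the track signal", {
  set.seed(37)
  b1 <- runif(2000, 0, 3); b2 <- runif(2000, 0, 3)
  t1 <- coverage_track(list(chr1 = b1), 50)
  t2 <- coverage_track(list(chr1 = b2), 50)
  tsum <- coverage_track(list(chr1 = b1 + b2), 50)
  iv <- genomic_intervals("chr1", c(20000, 50000, 80000),
                          c(24000, 54000, 84000))
  m1 <- metaprofile(t1, iv, "center", window = 3000)
  m2 <- metaprofile(t2, iv, "center", window = 3000)
  ms <- metaprofile(tsum, iv, "center", window = 3000)
  expect_equal(ms$mean_signal, m1$mean_signal + m2$mean_signal,
               tolerance = 1e-12)
  expect_error(metaprofile(t1, iv[0, ], "center"), "no anchors")
})
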