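test_that("3C interaction frequency follows the Ct-difference formula", {
  expect_equal(interaction_frequency(20, 20)$frequency, 1.0)
  expect_equal(interaction_frequency(23, 20)$frequency, 0.125)
  # each +1 cycle on Ct(3C) halves the frequency, across a Ct grid
  for (ct in seq(15, 30, by = 2.5)) {
    f0 <- interaction_frequency(ct, 20)$frequency
    f1 <- interaction_frequency(ct + 1, 20)$frequency
    expect_equal(f1, f0 / 2, tolerance = 1e-12)
  }
  # machine-offset invariance
  f <- interaction_frequency(c(22, 22.4), c(19.8, 20))$frequency
  fo <- interaction_frequency(c(22, 22.4) + 3, c(19.8, 20) + 3)$frequency
  expect_equal(fo, f, tolerance = 1e-12)
  expect_error(interaction_frequency(20, numeric()), "BAC")
})

test_that("3C replicate summaries quantify both error variants", {
  r <- interaction_frequency(c(22, 23, 22.5), c(20, 20.2, 19.8))
  expect_length(r$replicate_frequencies, 3)
  expect_gt(r$se, r$se_3c_only)
  r0 <- interaction_frequency(c(22, 22, 22), c(20, 20, 20))
  expect_equal(r0$se, 0)
})

test_that("percent input adjusts the input Ct for its dilution", {
  # chip Ct equal to the adjusted input Ct -> 100 percent
  f <- 0.01
  adj <- 25 - log2(1 / f)
  expect_equal(percent_input(ct_chip = adj, ct_input = 25,
                             input_fraction = f), 100)
  # five cycles later -> 100/32
  expect_equal(percent_input(adj + 5, 25, f), 3.125)
  # simulated pulldown with known efficiency is recovered
  d <- simulate_chip_qpcr(efficiency = 0.02, input_fraction = 0.01,
                          noise_sd = 0, seed = 1)
  got <- percent_input(d$ct[d$role == "chip"], d$ct[d$role == "input"],
                       input_fraction = 0.01)
  expect_equal(got, 2, tolerance = 1e-12)
  expect_error(percent_input(20, 20, input_fraction = 0), "> 0")
})

test_that("dual-luciferase double normalization is exact and scale-invariant", {
  expect_equal(dual_luciferase(200, 100, 50, 100), 4.0)
  expect_equal(dual_luciferase(123, 456, 123, 456), 1.0)
  base <- dual_luciferase(200, 100, 50, 100)
  for (k in c(0.01, 1, 250, 1e6)) {
    expect_equal(dual_luciferase(200 * k, 100 * k, 50 * k, 100 * k),
                 base, tolerance = 1e-12)
  }
  expect_error(dual_luciferase(200, 0, 50, 100), "Renilla")
  # noiseless simulated readings invert to the planted activity
  d <- simulate_luciferase(activity = 4, cv = 0, seed = 2)
  got <- dual_luciferase(d$firefly[d$construct == "test"][1],
                         d$renilla[d$construct == "test"][1],
                         d$firefly[d$construct == "vector"][1],
                         d$renilla[d$construct == "vector"][1])
  expect_equal(got, 4, tolerance = 1e-12)
})

test_that("delta-delta-Ct recovers relative expression", {
  expect_equal(ddct_fold_change(20, 18, 22, 18), 4.0)  # dCt 2 vs 4
  expect_equal(ddct_fold_change(20, 18, 20, 18), 1.0)
  # 16-fold planted template difference
  d <- simulate_qpcr_expression(c(treated = 16), noise_sd = 0, seed = 3)
  ct <- function(s, g) d$ct[d$sample == s & d$gene == g]
  got <- ddct_fold_change(ct("treated", "target"),
                          ct("treated", "reference"),
                          ct("control", "target"),
                          ct("control", "reference"))
  expect_equal(got, 16, tolerance = 1e-12)
  # noiseless 3C round trip, for symmetry
  freq <- c(F1 = 0.02, F4 = 0.4)
  q <- simulate_qpcr_3c(freq, noise_sd = 0, seed = 4)
  for (tg in names(freq)) {
    got <- interaction_frequency(q$ct[q$target == tg],
                                 q$ct[q$target == "BAC"])$frequency
    expect_equal(got, unname(freq[tg]), tolerance = 1e-12)
  }
})

test_that("nuclear signal is area times mean intensity", {
  m <- data.frame(nucleus_id = "n1", channel = "MGMT", area = 100,
                  mean_intensity = 2.0)
  expect_equal(nuclear_signal(m)$signal, 200)
  expect_error(nuclear_signal(data.frame(area = 0, mean_intensity = 1)),
               "> 0")
})

test_that("positive fraction classifies against fixed and derived thresholds", {
  m <- data.frame(nucleus_id = sprintf("n%d", 1:4), channel = "MGMT",
                  area = c(10, 10, 10, 10),
                  mean_intensity = c(1, 1, 5, 9))
  # all nuclei below a high fixed threshold
  expect_equal(positive_fraction(m, "MGMT", threshold = 1000)$fraction, 0)
  r <- positive_fraction(m, "MGMT", threshold = 30)
  expect_equal(r$fraction, 0.5)
  expect_equal(r$n, 4L)
  expect_error(positive_fraction(m, "Ki67", threshold = 1), "unknown")
  # planted mixture recovered within 0.05 using a negative-control rule
  sim <- simulate_nuclei(n = 100, positive_fraction = 0.24, seed = 5)
  est <- positive_fraction(sim$measurements, "MGMT",
                           negative_control = sim$negative_control)
  expect_lt(abs(est$fraction - 0.24), 0.05)
})

test_that("gating restricts the denominator to Ki67+/CD45- nuclei", {
  mk <- function(id, mgmt, ki67, cd45)
    data.frame(nucleus_id = id, channel = c("MGMT", "Ki67", "CD45"),
               area = 10, mean_intensity = c(mgmt, ki67, cd45))
  m <- rbind(mk("n1", 9, 9, 1),   # proliferating, MGMT+
             mk("n2", 9, 9, 9),   # CD45+: excluded
             mk("n3", 1, 9, 1),   # proliferating, MGMT-
             mk("n4", 1, 9, 1),   # proliferating, MGMT-
             mk("n5", 9, 1, 1),   # not proliferating: excluded
             mk("n6", 1, 9, 1))   # proliferating, MGMT-
  r <- positive_fraction(m, "MGMT", threshold = 30,
                         gate_positive = "Ki67", gate_negative = "CD45")
  expect_equal(r$n, 4L)           # n1, n3, n4, n6
  expect_equal(r$fraction, 0.25)  # only n1 is MGMT+
})

test_that("proliferation rate is the fold change relative to day 0", {
  r <- proliferation_rate(c(5, 5, 5, 5))
  expect_equal(r$fold_change, rep(1, 4))
  r2 <- proliferation_rate(c(5, 10, 20, 40))
  expect_equal(r2$fold_change, c(1, 2, 4, 8))
  expect_equal(attr(r2, "growth_rate"), 1, tolerance = 1e-12)
  # noisy exponential: log-linear slope within 10 percent of truth
  d <- simulate_confluency(rate_log2_per_day = 0.8, days = 6, cv = 0.05,
                           seed = 6)
  r3 <- proliferation_rate(d$confluency, d$day)
  expect_lt(abs(attr(r3, "growth_rate") - 0.8) / 0.8, 0.1)
  expect_error(proliferation_rate(c(0, 1, 2)), "day-0")
})
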