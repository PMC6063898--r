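## Synthetic assay tables with known planted parameters.
##
## Each generator inverts the corresponding calculator's formula to
## produce raw readings (Cts, luminescence, per-nucleus measurements,
## dose-response points) from planted values, plus measurement noise, so
## the calculators can be validated by round-trip recovery.

#' Simulate 3C qPCR Ct triplicates from planted interaction frequencies
#'
#' `Ct(3C) = Ct(BAC) - log2(frequency) + noise`, so
#' [interaction_frequency()] recovers the planted values exactly at zero
#' noise.
#'
#' @param frequencies Named vector of planted relative interaction
#'   frequencies (one per restriction fragment).
#' @param ct_bac_mean Mean BAC-control Ct (default 20).
#' @param noise_sd Gaussian Ct noise in cycles (default 0.1).
#' @param n_reps Replicates per target (default 3).
#' @param seed Integer seed.
#' @return Long data.frame with columns `target`, `role`
#'   (`test_3C`/`control_BAC`), `replicate`, `ct`.
#' @export
simulate_qpcr_3c <- function(frequencies, ct_bac_mean = 20,
                             noise_sd = 0.1, n_reps = 3, seed = 1) {
  if (is.null(names(frequencies)))
    names(frequencies) <- sprintf("F%d", seq_along(frequencies))
  local_seed(seed, {
    rows <- list(data.frame(target = "BAC", role = "control_BAC",
                            replicate = seq_len(n_reps),
                            ct = ct_bac_mean + rnorm(n_reps, 0, noise_sd)))
    for (tg in names(frequencies)) {
      rows[[tg]] <- data.frame(
        target = tg, role = "test_3C", replicate = seq_len(n_reps),
        ct = ct_bac_mean - log2(frequencies[[tg]]) +
          rnorm(n_reps, 0, noise_sd))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate RT-qPCR Cts from planted fold changes
#'
#' Target Cts drop by `log2(fold_change)` relative to the control
#' sample; reference-gene Cts are constant, so [ddct_fold_change()]
#' recovers the planted values exactly at zero noise.
#'
#' @param fold_changes Named vector of planted fold changes relative to
#'   the control sample (the control itself is added as `"control"`).
#' @param ct_gene_control,ct_reference Control-sample target Ct and
#'   reference-gene Ct.
#' @param noise_sd Gaussian Ct noise in cycles.
#' @param n_reps Replicates per (sample, gene).
#' @param seed Integer seed.
#' @return Long data.frame with `sample`, `gene` (`target`/`reference`),
#'   `replicate`, `ct`.
#' @export
simulate_qpcr_expression <- function(fold_changes, ct_gene_control = 25,
                                     ct_reference = 18, noise_sd = 0.1,
                                     n_reps = 3, seed = 1) {
  fcs <- c(control = 1, fold_changes)
  local_seed(seed, {
    rows <- lapply(names(fcs), function(s) {
      rbind(
        data.frame(sample = s, gene = "target",
                   replicate = seq_len(n_reps),
                   ct = ct_gene_control - log2(fcs[[s]]) +
                     rnorm(n_reps, 0, noise_sd)),
        data.frame(sample = s, gene = "reference",
                   replicate = seq_len(n_reps),
                   ct = ct_reference + rnorm(n_reps, 0, noise_sd)))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate ChIP-qPCR Cts from a planted pulldown efficiency
#'
#' Input and ChIP Cts are derived from the same template quantity: the
#' input represents `input_fraction` of chromatin and the ChIP sample
#' `efficiency` of it, so [percent_input()] recovers
#' `100 * efficiency`.
#'
#' @param efficiency Planted pulldown efficiency (fraction of chromatin
#'   recovered).
#' @param input_fraction Fraction of chromatin used as input.
#' @param ct_total Ct that the full chromatin amount would give.
#' @param noise_sd,n_reps,seed Noise, replication, seed.
#' @return data.frame with `role` (`chip`/`input`), `replicate`, `ct`.
#' @export
simulate_chip_qpcr <- function(efficiency = 0.02, input_fraction = 0.01,
                               ct_total = 15, noise_sd = 0.1, n_reps = 3,
                               seed = 1) {
  local_seed(seed, {
    out <- rbind(
      data.frame(role = "chip", replicate = seq_len(n_reps),
                 ct = ct_total - log2(efficiency) +
                   rnorm(n_reps, 0, noise_sd)),
      data.frame(role = "input", replicate = seq_len(n_reps),
                 ct = ct_total - log2(input_fraction) +
                   rnorm(n_reps, 0, noise_sd)))
    rownames(out) <- NULL
    out
  })
}

#' Simulate dual-luciferase readings from a planted relative activity
#'
#' @param activity Planted relative activity of the test construct
#'   (empty vector = 1).
#' @param vector_ratio Firefly/Renilla ratio of the empty vector.
#' @param renilla_level Mean Renilla reading (instrument units).
#' @param cv Coefficient of variation of the multiplicative reading
#'   noise.
#' @param n_reps,seed Replication and seed.
#' @return data.frame with `construct` (`test`/`vector`), `replicate`,
#'   `firefly`, `renilla`.
#' @export
simulate_luciferase <- function(activity = 4, vector_ratio = 0.5,
                                renilla_level = 1e5, cv = 0.05,
                                n_reps = 3, seed = 1) {
  local_seed(seed, {
    noisy <- function(mu, n) mu * exp(rnorm(n, 0, cv))
    out <- rbind(
      data.frame(construct = "test", replicate = seq_len(n_reps),
                 firefly = noisy(renilla_level * vector_ratio * activity,
                                 n_reps),
                 renilla = noisy(renilla_level, n_reps)),
      data.frame(construct = "vector", replicate = seq_len(n_reps),
                 firefly = noisy(renilla_level * vector_ratio, n_reps),
                 renilla = noisy(renilla_level, n_reps)))
    rownames(out) <- NULL
    out
  })
}

#' Simulate per-nucleus immunofluorescence measurements
#'
#' Two-component mixture: a planted fraction of nuclei is positive
#' (bright channel intensity), the rest sit at the negative background.
#'
#' @param n Number of nuclei.
#' @param positive_fraction Planted fraction of positive nuclei.
#' @param channel Channel label.
#' @param neg_intensity,pos_intensity Mean intensities of the two
#'   components.
#' @param area_mean Mean nuclear area (pixels).
#' @param cv Log-normal coefficient of variation of intensities and
#'   areas.
#' @param seed Integer seed.
#' @return List with `measurements` (columns `nucleus_id`, `channel`,
#'   `area`, `mean_intensity`), a matched `negative_control` set and the
#'   logical `truth` vector of planted positives.
#' @export
simulate_nuclei <- function(n = 100, positive_fraction = 0.24,
                            channel = "MGMT", neg_intensity = 1,
                            pos_intensity = 20, area_mean = 100,
                            cv = 0.2, seed = 1) {
  local_seed(seed, {
    n_pos <- round(n * positive_fraction)
    is_pos <- sample(c(rep(TRUE, n_pos), rep(FALSE, n - n_pos)))
    intensity <- ifelse(is_pos, pos_intensity, neg_intensity) *
      exp(rnorm(n, 0, cv))
    area <- area_mean * exp(rnorm(n, 0, cv))
    meas <- data.frame(nucleus_id = sprintf("nuc_%03d", seq_len(n)),
                       channel = channel, area = area,
                       mean_intensity = intensity,
                       stringsAsFactors = FALSE)
    nc <- data.frame(nucleus_id = sprintf("ctl_%03d", seq_len(n)),
                     channel = channel,
                     area = area_mean * exp(rnorm(n, 0, cv)),
                     mean_intensity = neg_intensity * exp(rnorm(n, 0, cv)),
                     stringsAsFactors = FALSE)
    list(measurements = meas, negative_control = nc, truth = is_pos)
  })
}

#' Simulate a dose-response viability table
#'
#' Points are generated from the four-parameter logistic with planted
#' parameters plus multiplicative Gaussian noise, so
#' [fit_dose_response()] can be validated by recovery.
#'
#' @param ic50,hill,bottom,top Planted 4PL parameters.
#' @param doses Dose levels (default: 0 plus a 7-point geometric series,
#'   matching a typical 0-1000 uM titration).
#' @param n_reps Replicates per dose.
#' @param cv Coefficient of variation of the response noise.
#' @param seed Integer seed.
#' @return data.frame with `dose` and `response`.
#' @export
simulate_dose_response <- function(ic50 = 10, hill = 1, bottom = 0,
                                   top = 1,
                                   doses = c(0, 1000 / 4^(6:0)),
                                   n_reps = 3, cv = 0.05, seed = 1) {
  local_seed(seed, {
    d <- rep(doses, each = n_reps)
    mu <- bottom + (top - bottom) / (1 + (d / ic50)^hill)
    data.frame(dose = d, response = mu * exp(rnorm(length(d), 0, cv)))
  })
}

#' Simulate a confluency time series
#'
#' Exponential growth at a planted per-day log2 rate with
#' multiplicative noise.
#'
#' @param rate_log2_per_day Planted growth rate (doublings per day).
#' @param days Number of days after day 0.
#' @param start Day-0 confluency (percent).
#' @param cv Noise coefficient of variation.
#' @param seed Integer seed.
#' @return data.frame with `day` and `confluency`.
#' @export
simulate_confluency <- function(rate_log2_per_day = 1, days = 6,
                                start = 5, cv = 0.05, seed = 1) {
  local_seed(seed, {
    day <- 0:days
    mu <- start * 2^(rate_log2_per_day * day)
    data.frame(day = day,
               confluency = mu * exp(rnorm(length(day), 0, cv)))
  })
}

#' Bundle of synthetic assay tables with planted parameters
#'
#' Generates one table per supported assay under a single seed, with
#' planted values chosen at the scale of typical enhancer-validation
#' experiments (a strong 3C contact at one fragment, a 16-fold
#' expression change, a 0.24 positive-cell fraction, a 10 uM IC50).
#'
#' @param seed Integer seed.
#' @param noise_sd Ct noise (cycles) for the qPCR tables.
#' @param cv Multiplicative noise for luminescence/viability tables.
#' @return List with one element per assay, each a list of `data` and
#'   `planted` parameters.
#' @export
simulate_assays <- function(seed = 1, noise_sd = 0.1, cv = 0.05) {
  freq <- c(F1 = 0.02, F2 = 0.03, F3 = 0.05, F4 = 0.40, F5 = 0.04,
            F6 = 0.02)
  fc <- c(treated = 16)
  list(
    qpcr_3c = list(
      data = simulate_qpcr_3c(freq, noise_sd = noise_sd, seed = seed),
      planted = list(frequencies = freq)),
    qpcr_expression = list(
      data = simulate_qpcr_expression(fc, noise_sd = noise_sd,
                                      seed = seed + 1),
      planted = list(fold_changes = fc)),
    chip_qpcr = list(
      data = simulate_chip_qpcr(efficiency = 0.02, noise_sd = noise_sd,
                                seed = seed + 2),
      planted = list(efficiency = 0.02, input_fraction = 0.01)),
    luciferase = list(
      data = simulate_luciferase(activity = 4, cv = cv, seed = seed + 3),
      planted = list(activity = 4)),
    nuclei = c(simulate_nuclei(positive_fraction = 0.24, seed = seed + 4),
               list(planted = list(positive_fraction = 0.24))),
    dose_response = list(
      data = simulate_dose_response(ic50 = 10, cv = cv, seed = seed + 5),
      planted = list(ic50 = 10, hill = 1, bottom = 0, top = 1)),
    confluency = list(
      data = simulate_confluency(rate_log2_per_day = 1, cv = cv,
                                 seed = seed + 6),
      planted = list(rate_log2_per_day = 1)))
}
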