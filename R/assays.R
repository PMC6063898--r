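## Bench-assay quantification: pure table-in / table-out calculators.
##
## All qPCR formulas assume perfect doubling per cycle (efficiency 2.0);
## none applies an efficiency correction.

#' 3C relative interaction frequency
#'
#' Quantifies a chromosome-conformation-capture ligation product against
#' the BAC control template: `frequency = 2^(Ct(BAC) - Ct(3C))` using
#' replicate-mean Cts. Adding a constant to all Cts (a machine offset)
#' leaves the frequency unchanged.
#'
#' @param ct_3c Numeric replicate Ct values of the 3C ligation product.
#' @param ct_bac Numeric replicate Ct values of the BAC control
#'   ligation.
#' @return List with `frequency`, per-replicate `replicate_frequencies`
#'   (each 3C replicate against the mean BAC Ct), `se` (standard error
#'   propagating both replicate variances by the delta method on the
#'   log2 scale) and `se_3c_only` (3C replicate variance only).
#' @export
interaction_frequency <- function(ct_3c, ct_bac) {
  if (!length(ct_bac)) stop("missing BAC control Cts", call. = FALSE)
  if (!length(ct_3c)) stop("missing 3C Cts", call. = FALSE)
  if (any(c(ct_3c, ct_bac) <= 0)) stop("Ct values must be > 0",
                                       call. = FALSE)
  f <- 2^(mean(ct_bac) - mean(ct_3c))
  reps <- 2^(mean(ct_bac) - ct_3c)
  v_log2 <- function(x) if (length(x) > 1) var(x) / length(x) else 0
  se_both <- f * log(2) * sqrt(v_log2(ct_bac) + v_log2(ct_3c))
  se_3c <- f * log(2) * sqrt(v_log2(ct_3c))
  list(frequency = f, replicate_frequencies = reps,
       se = se_both, se_3c_only = se_3c)
}

#' ChIP-qPCR percent input
#'
#' Normalizes an immunoprecipitated sample against its input: the input
#' Ct is first adjusted for the fraction of chromatin it represents
#' (`Ct_input - log2(1/input_fraction)`), then
#' `percent = 100 * 2^(adjusted Ct(input) - Ct(chip))`.
#'
#' @param ct_chip,ct_input Replicate Ct values (means are used).
#' @param input_fraction Fraction of chromatin used as input, in (0, 1]
#'   (default 0.01, i.e. a one-percent input).
#' @return Percent-input enrichment (100 = full recovery).
#' @export
percent_input <- function(ct_chip, ct_input, input_fraction = 0.01) {
  stopifnot_scalar_number(input_fraction, "input_fraction", 0, TRUE)
  if (input_fraction > 1) stop("'input_fraction' must be <= 1",
                               call. = FALSE)
  adj_input <- mean(ct_input) - log2(1 / input_fraction)
  100 * 2^(adj_input - mean(ct_chip))
}

#' Dual-luciferase relative activity
#'
#' Firefly activity is normalized to the Renilla co-transfection control
#' first, then to the empty-vector control:
#' `(firefly_test/renilla_test) / (firefly_vector/renilla_vector)`.
#' Rescaling all four readings by any instrument constant leaves the
#' result unchanged.
#'
#' @param firefly_test,renilla_test Readings for the test construct.
#' @param firefly_vector,renilla_vector Readings for the empty vector.
#' @return Relative luciferase activity (vector control = 1).
#' @export
dual_luciferase <- function(firefly_test, renilla_test,
                            firefly_vector, renilla_vector) {
  vals <- c(firefly_test, renilla_test, firefly_vector, renilla_vector)
  if (any(vals <= 0))
    stop("all luciferase readings must be > 0 (zero Renilla indicates a ",
         "failed transfection)", call. = FALSE)
  (firefly_test / renilla_test) / (firefly_vector / renilla_vector)
}

#' Delta-delta-Ct relative expression
#'
#' Target expression is normalized to a reference gene within each
#' sample and expressed as fold change relative to a control sample:
#' `2^-((Ct_gene - Ct_ref) - (Ct_gene_control - Ct_ref_control))`.
#' Replicate Cts are averaged; a shared machine offset cancels.
#'
#' @param ct_gene,ct_reference Sample Cts for target and reference gene.
#' @param ct_gene_control,ct_reference_control Control-sample Cts.
#' @return Fold change relative to the control sample.
#' @export
ddct_fold_change <- function(ct_gene, ct_reference,
                             ct_gene_control, ct_reference_control) {
  d_sample <- mean(ct_gene) - mean(ct_reference)
  d_control <- mean(ct_gene_control) - mean(ct_reference_control)
  2^(-(d_sample - d_control))
}

#' Per-nucleus immunofluorescence signal
#'
#' `signal = area * mean_intensity`, computed per nucleus.
#'
#' @param measurements data.frame with columns `area` and
#'   `mean_intensity` (and typically `nucleus_id`, `channel`).
#' @return The input with a `signal` column appended.
#' @export
nuclear_signal <- function(measurements) {
  if (!all(c("area", "mean_intensity") %in% names(measurements)))
    stop("measurements need 'area' and 'mean_intensity' columns",
         call. = FALSE)
  if (any(measurements$area <= 0)) stop("area must be > 0", call. = FALSE)
  if (any(measurements$mean_intensity < 0))
    stop("mean_intensity must be >= 0", call. = FALSE)
  measurements$signal <- measurements$area * measurements$mean_intensity
  measurements
}

#' Fraction of positive nuclei
#'
#' Classifies nuclei as positive for a channel when their total signal
#' (area x mean intensity) exceeds a threshold, and returns the positive
#' fraction. The threshold is either given directly or derived as
#' `k * median(signal)` of a negative-control measurement set. Optional
#' gating restricts the denominator to nuclei positive for
#' `gate_positive` channels and negative for `gate_negative` channels
#' (e.g. proliferating tumor cells: Ki67-positive, CD45-negative).
#'
#' @param measurements Long data.frame with columns `nucleus_id`,
#'   `channel`, `area`, `mean_intensity`.
#' @param channel Channel to score.
#' @param threshold Fixed signal threshold, or `NULL` to derive one.
#' @param negative_control Measurement set (same format) used when
#'   deriving the threshold.
#' @param k Multiplier on the negative-control median (default 3).
#' @param gate_positive,gate_negative Character vectors of channels a
#'   nucleus must be positive/negative for (scored with the same rule)
#'   to enter the denominator.
#' @return List with `fraction`, `n` (denominator), `n_positive` and the
#'   per-channel `thresholds` used.
#' @export
positive_fraction <- function(measurements, channel, threshold = NULL,
                              negative_control = NULL, k = 3,
                              gate_positive = NULL, gate_negative = NULL) {
  m <- nuclear_signal(measurements)
  channels <- unique(m$channel)
  needed <- c(channel, gate_positive, gate_negative)
  unknown <- setdiff(needed, channels)
  if (length(unknown))
    stop("unknown channel(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  thr_for <- function(ch) {
    if (!is.null(threshold)) return(threshold)
    if (is.null(negative_control))
      stop("supply either a fixed 'threshold' or a 'negative_control' set",
           call. = FALSE)
    nc <- nuclear_signal(negative_control)
    ncs <- nc$signal[nc$channel == ch]
    if (!length(ncs)) ncs <- nc$signal
    k * median(ncs)
  }
  pos_ids <- function(ch) {
    s <- m[m$channel == ch, , drop = FALSE]
    s$nucleus_id[s$signal > thr_for(ch)]
  }
  ids <- unique(m$nucleus_id[m$channel == channel])
  for (ch in gate_positive) ids <- intersect(ids, pos_ids(ch))
  for (ch in gate_negative) ids <- setdiff(ids, pos_ids(ch))
  if (!length(ids))
    return(list(fraction = NA_real_, n = 0L, n_positive = 0L,
                thresholds = setNames(vapply(needed, thr_for, numeric(1)),
                                      needed)))
  npos <- length(intersect(ids, pos_ids(channel)))
  list(fraction = npos / length(ids), n = length(ids),
       n_positive = npos,
       thresholds = setNames(vapply(needed, thr_for, numeric(1)), needed))
}

#' Proliferation rate from a confluency series
#'
#' Fold change in confluency each day relative to day 0.
#'
#' @param confluency Numeric confluency values.
#' @param day Numeric day labels (must include day 0).
#' @return data.frame with `day` and `fold_change` (day 0 = 1); the
#'   attribute `growth_rate` carries the log-linear slope (log2 units
#'   per day).
#' @export
proliferation_rate <- function(confluency, day = seq_along(confluency) - 1) {
  if (length(confluency) != length(day))
    stop("confluency and day must have equal length", call. = FALSE)
  o <- order(day)
  day <- day[o]; confluency <- confluency[o]
  if (day[1] != 0) stop("series must start at day 0", call. = FALSE)
  if (confluency[1] <= 0)
    stop("day-0 confluency must be > 0", call. = FALSE)
  out <- data.frame(day = day, fold_change = confluency / confluency[1])
  pos <- confluency > 0
  if (sum(pos) >= 2) {
    fit <- stats::lm(log2(confluency[pos]) ~ day[pos])
    attr(out, "growth_rate") <- unname(coef(fit)[2])
  }
  out
}
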