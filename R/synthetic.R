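#' Empirical level weights of the bundled cohort
#'
#' Per-criterion categorical frequencies of the evidence levels observed in
#' the bundled 48-disorder evaluation, used as the default sampling weights
#' of [generate_cohort()] so that synthetic cohorts resemble the reference
#' score distribution.
#'
#' @param cohort an evidence table to take frequencies from.
#' @return Named list of named probability vectors, one per evidence field
#'   (`severity_level`, `onset_class`, `frequency_band`, `dbs_status`,
#'   `performance_class`, `treatment_availability`, `outcomes_level`,
#'   `disorder_class`). `frequency_band` weights are over the frequency
#'   criterion points (`"2"`, `"1.5"`, `"1"`, `"0.5"`, `"0"`).
#' @export
fixture_level_weights <- function(cohort = imd_cohort()) {
  freq_pts <- fmt_pts(score_frequency(cohort$prevalence))
  wt <- function(x, choices) {
    tab <- table(factor(x, levels = choices))
    as.numeric(tab / sum(tab)) |> stats::setNames(choices)
  }
  rubric <- default_rubric()
  crits <- rubric_criteria(rubric)
  codes <- function(nm) vapply(crits[[nm]]$criterion$levels, `[[`,
                               character(1), "code")
  list(
    severity_level = wt(cohort$severity_level, codes("severity")),
    onset_class = wt(cohort$onset_class, onset_classes),
    frequency_band = wt(freq_pts, c("2", "1.5", "1", "0.5", "0")),
    dbs_status = wt(cohort$dbs_status, dbs_statuses),
    performance_class = wt(cohort$performance_class, performance_classes),
    treatment_availability = wt(cohort$treatment_availability,
                                treatment_availability_classes),
    outcomes_level = wt(cohort$outcomes_level, codes("treat_outcomes")),
    disorder_class = wt(cohort$disorder_class, disorder_class_labels))
}

sample_level <- function(n, weights, what) {
  if (any(is.na(weights)) || any(weights < 0) || sum(weights) <= 0) {
    stop(sprintf("invalid level weights for %s: must be non-negative and sum to a positive value",
                 what), call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-6) {
    stop(sprintf("level weights for %s must sum to 1 (got %g)", what,
                 sum(weights)), call. = FALSE)
  }
  sample(names(weights), n, replace = TRUE, prob = weights)
}

#' Generate a synthetic evidence cohort
#'
#' Draws `n` synthetic disorder evidence records whose levels are sampled
#' from per-criterion categorical weights (by default the empirical level
#' frequencies of the bundled 48-disorder cohort). Birth prevalence is
#' drawn by first sampling a frequency band and then a value uniformly
#' within that band intersected with `prevalence_range`; the zero band
#' yields an absent estimate. The screening and treatment cross-field
#' invariants are enforced during sampling (no DBS assay implies no
#' performance claim; no treatment implies the zero-point outcomes level),
#' so every generated cohort passes [validate_cohort()]. With the same seed
#' the output is identical.
#'
#' @param n cohort size.
#' @param seed integer seed for reproducible sampling; `NULL` uses the
#'   current RNG state.
#' @param level_weights per-criterion sampling weights, as returned by
#'   [fixture_level_weights()].
#' @param prevalence_range bounds for sampled prevalences (cases per
#'   birth).
#' @return An evidence tibble of `n` rows with ids `syn001`, `syn002`, ...
#' @examples
#' cohort <- generate_cohort(n = 5, seed = 42)
#' score_cohort(cohort)$total
#' @export
generate_cohort <- function(n = 48, seed = NULL,
                            level_weights = fixture_level_weights(),
                            prevalence_range = c(1 / 2e6, 1 / 1e4)) {
  stopifnot(length(n) == 1L, n >= 0)
  n <- as.integer(n)
  draw <- function() {
    band_lo <- c("2" = 1 / 50000, "1.5" = 1 / 100000, "1" = 1 / 150000,
                 "0.5" = 1 / 250000)
    band_hi <- c("2" = Inf, "1.5" = 1 / 50000, "1" = 1 / 100000,
                 "0.5" = 1 / 150000)
    band <- sample_level(n, level_weights$frequency_band, "frequency_band")
    prevalence <- rep(NA_real_, n)
    for (i in which(band != "0")) {
      lo <- max(band_lo[[band[i]]], prevalence_range[1])
      hi <- min(band_hi[[band[i]]], prevalence_range[2])
      prevalence[i] <- stats::runif(1, lo, hi)
    }
    dbs <- sample_level(n, level_weights$dbs_status, "dbs_status")
    perf <- sample_level(n, level_weights$performance_class,
                         "performance_class")
    perf[dbs == "none"] <- "insufficient_or_none"
    treat <- sample_level(n, level_weights$treatment_availability,
                          "treatment_availability")
    outc <- sample_level(n, level_weights$outcomes_level, "outcomes_level")
    outc[treat == "none"] <- "O0"
    tibble::tibble(
      disorder_id = sprintf("syn%03d", seq_len(n)),
      name = sprintf("Synthetic disorder %03d", seq_len(n)),
      disorder_class = sample_level(n, level_weights$disorder_class,
                                    "disorder_class"),
      severity_level = sample_level(n, level_weights$severity_level,
                                    "severity_level"),
      onset_class = sample_level(n, level_weights$onset_class,
                                 "onset_class"),
      prevalence = prevalence,
      prevalence_provenance = "unknown",
      dbs_status = dbs,
      performance_class = perf,
      treatment_availability = treat,
      outcomes_level = outc)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
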