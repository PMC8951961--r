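# Birth-prevalence bands, highest first. A prevalence maps to the first band
# whose lower bound it reaches: the top band is closed at 1/50,000, the
# intermediate bands are half-open [lower, upper), and anything below
# 1/250,000 — or no estimate at all — scores 0.
frequency_bands <- function() {
  data.frame(points = c(2, 1.5, 1, 0.5),
             min_prevalence = c(1 / 50000, 1 / 100000, 1 / 150000,
                                1 / 250000))
}

#' Score the frequency criterion from birth prevalence
#'
#' Maps a birth prevalence (cases per birth) to the rubric's frequency
#' points: `>= 1/50,000` scores 2; `[1/100,000, 1/50,000)` scores 1.5;
#' `[1/150,000, 1/100,000)` scores 1; `[1/250,000, 1/150,000)` scores 0.5;
#' below `1/250,000` or no estimate scores 0. Non-decreasing in prevalence.
#'
#' @param prevalence numeric vector of prevalences; `NA` means no estimate.
#' @param rubric the scoring rubric (the band points must be levels of its
#'   frequency criterion).
#' @return Numeric vector of points.
#' @examples
#' score_frequency(c(1 / 50000, 1 / 120000, NA))
#' @export
score_frequency <- function(prevalence, rubric = default_rubric()) {
  bands <- frequency_bands()
  vapply(as.numeric(prevalence), function(p) {
    if (is.na(p)) return(0)
    hit <- which(p >= bands$min_prevalence)
    if (length(hit)) bands$points[min(hit)] else 0
  }, numeric(1))
}

lookup_level <- function(crits, criterion, code, what = criterion) {
  pts <- level_points(crits[[criterion]]$criterion, code)
  if (is.na(pts)) {
    stop(sprintf("unknown %s code '%s'", what, as.character(code)),
         call. = FALSE)
  }
  pts
}

#' Score the Condition pillar criteria
#'
#' Severity is a curated ordinal pass-through (the level code's points);
#' onset scores 2 when all forms of the disorder are asymptomatic in the
#' first weeks of life, 1 when only some forms are, 0 otherwise; frequency
#' is banded birth prevalence via [score_frequency()].
#'
#' @param ev a list or one-row data frame with `severity_level`,
#'   `onset_class` and `prevalence`.
#' @param rubric the scoring rubric.
#' @return Named numeric of length 3: `severity`, `onset`, `frequency`.
#' @export
score_condition <- function(ev, rubric = default_rubric()) {
  crits <- rubric_criteria(rubric)
  c(severity = lookup_level(crits, "severity", ev$severity_level),
    onset = lookup_level(crits, "onset", ev$onset_class, "onset class"),
    frequency = score_frequency(ev$prevalence %||% NA_real_, rubric))
}

#' Score the Screening pillar criteria
#'
#' Availability: a DBS assay in use in a public programme or CE-marked /
#' FDA-approved scores 2, an assay in development 1, none 0. Performance: a
#' low false-positive rate standalone scores 1, an available second-tier
#' confirmatory strategy 0.5, insufficient or no data 0.
#'
#' @inheritParams score_condition
#' @param ev a list or one-row data frame with `dbs_status` and
#'   `performance_class`.
#' @return Named numeric of length 2: `screen_availability`,
#'   `screen_performance`.
#' @export
score_screening <- function(ev, rubric = default_rubric()) {
  crits <- rubric_criteria(rubric)
  c(screen_availability = lookup_level(crits, "screen_availability",
                                       ev$dbs_status, "dbs_status"),
    screen_performance = lookup_level(crits, "screen_performance",
                                      ev$performance_class,
                                      "performance class"))
}

#' Score the Treatment pillar criteria
#'
#' Availability reflects the highest-scoring treatment strategy: an
#' EMA-approved treatment scores 1.5, a phase III investigational treatment
#' or an intervention (diet, HSCT, BMT) 1, a limited intervention 0.5, none
#' 0. Outcomes is a curated ordinal pass-through. A disorder with no
#' treatment strategy cannot carry outcomes points.
#'
#' @inheritParams score_condition
#' @param ev a list or one-row data frame with `treatment_availability` and
#'   `outcomes_level`.
#' @return Named numeric of length 2: `treat_availability`,
#'   `treat_outcomes`.
#' @export
score_treatment <- function(ev, rubric = default_rubric()) {
  crits <- rubric_criteria(rubric)
  avail <- lookup_level(crits, "treat_availability",
                        ev$treatment_availability,
                        "treatment availability class")
  outc <- lookup_level(crits, "treat_outcomes", ev$outcomes_level,
                       "outcomes level")
  if (half_units(avail) == 0L && half_units(outc) != 0L) {
    stop("treatment availability 'none' is inconsistent with nonzero outcomes points",
         call. = FALSE)
  }
  c(treat_availability = avail, treat_outcomes = outc)
}

#' Score one disorder's evidence to a scorecard
#'
#' Applies the three pillar scorers and aggregates: pillar sums are the sums
#' of their criterion sub-scores (capped by construction at 6, 3 and 4) and
#' the total is the sum of the pillar sums, in `[0, 13]` half-point steps.
#'
#' @param ev a list or one-row data frame with the evidence fields (see
#'   [read_evidence()]).
#' @param rubric the scoring rubric.
#' @return A `scorecard`: list with `disorder_id`, `sub_scores` (named
#'   numeric of 7), `pillar_sums` (named numeric of 3) and `total`.
#' @examples
#' ev <- generate_cohort(n = 1, seed = 1)
#' score_disorder(ev)
#' @export
score_disorder <- function(ev, rubric = default_rubric()) {
  sub <- c(score_condition(ev, rubric), score_screening(ev, rubric),
           score_treatment(ev, rubric))
  pillar_sums <- c(
    condition = sum(sub[c("severity", "onset", "frequency")]),
    screening = sum(sub[c("screen_availability", "screen_performance")]),
    treatment = sum(sub[c("treat_availability", "treat_outcomes")]))
  caps <- vapply(rubric$pillars, `[[`, numeric(1), "cap")
  names(caps) <- vapply(rubric$pillars, `[[`, character(1), "name")
  stopifnot(all(half_units(pillar_sums) <= half_units(caps[names(pillar_sums)])))
  structure(list(disorder_id = ev$disorder_id %||% NA_character_,
                 sub_scores = sub,
                 pillar_sums = pillar_sums,
                 total = sum(pillar_sums)),
            class = "scorecard")
}

#' @export
print.scorecard <- function(x, ...) {
  cat(sprintf("<scorecard> %s: total %s (condition %s, screening %s, treatment %s)\n",
              x$disorder_id, fmt_pts(x$total),
              fmt_pts(x$pillar_sums[["condition"]]),
              fmt_pts(x$pillar_sums[["screening"]]),
              fmt_pts(x$pillar_sums[["treatment"]])))
  print(x$sub_scores)
  invisible(x)
}

#' Score a cohort of disorders
#'
#' Validates the cohort, scores every record and returns a score table, one
#' row per disorder in input order. Deterministic: identical input yields
#' identical output.
#'
#' @param cohort evidence table (extra columns are ignored).
#' @param rubric the scoring rubric.
#' @return A tibble with columns `disorder_id`, `name`, `disorder_class`,
#'   the seven sub-scores (`severity`, `onset`, `frequency`,
#'   `screen_availability`, `screen_performance`, `treat_availability`,
#'   `treat_outcomes`), the pillar sums (`condition_sum`, `screening_sum`,
#'   `treatment_sum`) and `total`.
#' @examples
#' scores <- score_cohort(imd_cohort())
#' head(scores[, c("disorder_id", "total")])
#' @export
score_cohort <- function(cohort, rubric = default_rubric()) {
  violations <- validate_cohort(cohort, rubric)
  if (length(violations)) {
    stop("cohort failed validation:\n",
         paste("-", violations, collapse = "\n"), call. = FALSE)
  }
  n <- nrow(cohort)
  sub <- matrix(NA_real_, nrow = n, ncol = 7,
                dimnames = list(NULL, c("severity", "onset", "frequency",
                                        "screen_availability",
                                        "screen_performance",
                                        "treat_availability",
                                        "treat_outcomes")))
  for (i in seq_len(n)) {
    card <- score_disorder(as.list(cohort[i, , drop = FALSE]), rubric)
    sub[i, ] <- card$sub_scores[colnames(sub)]
  }
  out <- tibble::tibble(
    disorder_id = cohort$disorder_id,
    name = cohort$name,
    disorder_class = cohort$disorder_class)
  out <- cbind(out, tibble::as_tibble(as.data.frame(sub)))
  out$condition_sum <- out$severity + out$onset + out$frequency
  out$screening_sum <- out$screen_availability + out$screen_performance
  out$treatment_sum <- out$treat_availability + out$treat_outcomes
  out$total <- out$condition_sum + out$screening_sum + out$treatment_sum
  tibble::as_tibble(out)
}
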