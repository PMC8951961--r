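#' The bundled reference evaluation of 48 IMDs
#'
#' Loads the packaged cohort of 48 inherited metabolic disorders curated as
#' candidates for expanded newborn screening across Europe. Each record
#' carries the evidence fields the rubric scores (see [read_evidence()])
#' together with the reference seven sub-scores and total (`printed_*`
#' columns) from the original evaluation, so the scoring engine can be
#' checked against them. Disorder classes: 20 lysosomal storage disorders
#' (LSD), 8 disorders of organic acid metabolism (DOAM), 7 of amino acid
#' metabolism (DAAM), 9 of fatty acid metabolism (DFAM) and 4 other (SCID,
#' GALT, BIOT, X-ALD).
#'
#' The per-disorder birth-prevalence estimates behind the frequency
#' sub-scores are not distributed with the cohort; the `prevalence` column
#' holds synthetic band-representative values (1/40,000, 1/75,000,
#' 1/120,000, 1/200,000, or absent for the zero band) with provenance
#' `"unknown"`. They reproduce the reference frequency points under
#' [score_frequency()] but are not the curated estimates themselves.
#'
#' @return A 48-row tibble: the evidence columns of [read_evidence()] plus
#'   `printed_severity`, `printed_onset`, `printed_frequency`,
#'   `printed_screen_availability`, `printed_screen_performance`,
#'   `printed_treat_availability`, `printed_treat_outcomes`,
#'   `printed_total`.
#' @examples
#' fx <- imd_cohort()
#' nrow(fx)
#' fx[fx$disorder_id == "cud", c("name", "printed_total")]
#' @export
imd_cohort <- function() {
  path <- system.file("extdata", "imd_evaluation.csv", package = "nbspanel",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(prevalence = "character"),
                        fileEncoding = "UTF-8")
  df$prevalence <- parse_prevalence(df$prevalence)
  tibble::as_tibble(df)
}
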