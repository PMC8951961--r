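Package: nbspanel
Title: Prioritizing Inherited Metabolic Disorders for Newborn Screening Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A weighted ordinal rubric for evaluating and ranking inherited
    metabolic disorders (IMDs) as candidates for newborn screening (NBS)
    panels, following the Wilson-Jungner screening principles. Three pillars
    (Condition, Screening, Treatment) with capped criterion scores are
    aggregated to a 0-13 point total; disorders at or above a recommendation
    threshold (default 8.5) are flagged for panel inclusion. Includes a
    bundled reference evaluation of 48 IMDs, birth-prevalence banding,
    cohort summary statistics, threshold-sweep and criterion-ablation
    sensitivity analytics with Kendall tau-b rank concordance, a seeded
    synthetic evidence generator, and CSV/YAML interfaces for user-supplied
    evidence tables and rubric configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
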