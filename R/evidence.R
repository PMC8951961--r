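# Closed vocabularies for the enumerated evidence fields.
onset_classes <- c("all_forms_asymptomatic_first_weeks",
                   "some_forms_asymptomatic",
                   "symptomatic_at_birth_or_unknown")
dbs_statuses <- c("in_use_or_registered", "in_development", "none")
performance_classes <- c("low_fp_standalone", "second_tier_available",
                         "insufficient_or_none")
treatment_availability_classes <- c("ema_approved", "phase3_or_intervention",
                                    "limited_intervention", "none")
disorder_class_labels <- c("LSD", "DOAM", "DAAM", "DFAM", "other")
prevalence_provenances <- c("european", "worldwide", "us", "unknown")

evidence_columns <- c("disorder_id", "name", "disorder_class",
                      "severity_level", "onset_class", "prevalence",
                      "prevalence_provenance", "dbs_status",
                      "performance_class", "treatment_availability",
                      "outcomes_level")

# case-insensitive match into a closed vocabulary; NA if no match
match_enum <- function(x, choices) {
  choices[match(tolower(trimws(x)), tolower(choices))]
}

#' Parse birth prevalence notation
#'
#' Accepts a decimal fraction (`"2e-05"`, `"0.00002"`) or `"1/N"` notation
#' (`"1/50000"`, thousands separators allowed). Empty strings and `NA` mean
#' no estimate is available.
#'
#' @param x character or numeric vector.
#' @return Numeric vector of prevalences as cases per birth.
#' @examples
#' parse_prevalence(c("1/50000", "2e-05", ""))
#' @export
parse_prevalence <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  blank <- is.na(x) | x == ""
  ratio <- !blank & grepl("^1\\s*/\\s*[0-9,]+$", x)
  if (any(ratio)) {
    denom <- as.numeric(gsub("[^0-9]", "", sub("^1\\s*/", "", x[ratio])))
    out[ratio] <- 1 / denom
  }
  dec <- !blank & !ratio
  if (any(dec)) {
    val <- suppressWarnings(as.numeric(x[dec]))
    if (anyNA(val)) {
      stop("unparseable prevalence value(s): ",
           paste(x[dec][is.na(val)], collapse = ", "), call. = FALSE)
    }
    out[dec] <- val
  }
  out
}

#' Read and write disorder evidence tables
#'
#' An evidence table holds one row per candidate disorder with the curated
#' facts the rubric scores: disorder identity and class, a severity level
#' code, an onset class, a birth prevalence estimate with provenance,
#' dried-blood-spot assay status and performance class, treatment
#' availability class and an outcomes level code. Columns are
#' `r paste(evidence_columns, collapse = ", ")`. Enumerated fields are
#' parsed case-insensitively; prevalence accepts decimal or `"1/N"`
#' notation. Every parsed table is checked with [validate_cohort()] and
#' rejected if any row breaks an invariant.
#'
#' @param source path to a CSV/TSV file, or literal delimited text.
#' @param delim field delimiter; inferred from the file extension (`.tsv`
#'   reads as tab) when omitted, comma otherwise.
#' @param rubric rubric supplying valid severity/outcomes level codes.
#' @return A tibble with the evidence columns, prevalence as a numeric
#'   fraction (`NA` when absent).
#' @examples
#' tab <- write_evidence(generate_cohort(n = 3, seed = 1))
#' read_evidence(tab)
#' @export
read_evidence <- function(source, delim = NULL, rubric = default_rubric()) {
  is_file <- length(source) == 1L && !grepl("\n", source)
  if (is.null(delim)) {
    delim <- if (is_file && grepl("\\.tsv$", source, ignore.case = TRUE)) {
      "\t"
    } else ","
  }
  df <- if (is_file) {
    utils::read.table(source, sep = delim, header = TRUE,
                      colClasses = "character", check.names = FALSE,
                      quote = "\"", fileEncoding = "UTF-8")
  } else {
    utils::read.table(text = source, sep = delim, header = TRUE,
                      colClasses = "character", check.names = FALSE,
                      quote = "\"")
  }

  missing <- setdiff(evidence_columns, names(df))
  if (length(missing)) {
    stop("evidence table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(df), evidence_columns)
  if (length(unknown)) {
    stop("evidence table schema error: unknown column(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  df <- df[evidence_columns]

  ev <- tibble::tibble(
    disorder_id = trimws(df$disorder_id),
    name = trimws(df$name),
    disorder_class = match_enum(df$disorder_class, disorder_class_labels),
    severity_level = trimws(df$severity_level),
    onset_class = match_enum(df$onset_class, onset_classes),
    prevalence = parse_prevalence(df$prevalence),
    prevalence_provenance = ifelse(
      is.na(df$prevalence_provenance) | df$prevalence_provenance == "",
      "unknown", match_enum(df$prevalence_provenance,
                            prevalence_provenances)),
    dbs_status = match_enum(df$dbs_status, dbs_statuses),
    performance_class = match_enum(df$performance_class,
                                   performance_classes),
    treatment_availability = match_enum(df$treatment_availability,
                                        treatment_availability_classes),
    outcomes_level = trimws(df$outcomes_level))

  violations <- validate_cohort(ev, rubric)
  if (length(violations)) {
    stop("invalid evidence table:\n",
         paste("-", violations, collapse = "\n"), call. = FALSE)
  }
  ev
}

#' @rdname read_evidence
#' @param cohort evidence table (as returned by `read_evidence()` or
#'   [generate_cohort()]).
#' @param path optional output file path.
#' @export
write_evidence <- function(cohort, path = NULL, delim = ",") {
  out <- as.data.frame(cohort)[evidence_columns]
  out$prevalence <- ifelse(is.na(out$prevalence), "",
                           sprintf("%.15g", out$prevalence))
  con <- textConnection("txt", "w", local = TRUE)
  utils::write.table(out, con, sep = delim, row.names = FALSE,
                     qmethod = "double")
  close(con)
  txt <- paste0(paste(txt, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(txt, path, sep = "", useBytes = TRUE)
  invisible(txt)
}

#' Validate a cohort of disorder evidence records
#'
#' Checks per-record and cross-record invariants: unique `disorder_id`;
#' enumerated fields from their closed vocabularies; severity and outcomes
#' codes valid under the rubric; prevalence in `[0, 1]` or absent; no
#' screening performance claim without a DBS assay (`dbs_status == "none"`
#' forces `performance_class == "insufficient_or_none"`); and no outcomes
#' points without a treatment strategy (`treatment_availability == "none"`
#' forces the zero-point outcomes code).
#'
#' @param cohort evidence table.
#' @param rubric rubric supplying valid level codes.
#' @return Character vector of violations with row numbers; empty if clean.
#' @export
validate_cohort <- function(cohort, rubric = default_rubric()) {
  v <- character(0)
  say <- function(...) v <<- c(v, sprintf(...))
  n <- nrow(cohort)
  if (n == 0L) return(v)

  dup <- unique(cohort$disorder_id[duplicated(cohort$disorder_id)])
  if (length(dup)) {
    say("duplicate disorder_id: %s", paste(dup, collapse = ", "))
  }

  crits <- rubric_criteria(rubric)
  sev_codes <- vapply(crits$severity$criterion$levels, `[[`, character(1),
                      "code")
  out_codes <- vapply(crits$treat_outcomes$criterion$levels, `[[`,
                      character(1), "code")
  out_zero <- out_codes[criterion_level_points(
    crits$treat_outcomes$criterion) == 0]

  check_enum <- function(col, choices, what) {
    bad <- which(is.na(cohort[[col]]) | !(cohort[[col]] %in% choices))
    for (i in bad) say("row %d (%s): invalid %s '%s'", i,
                       cohort$disorder_id[i], what,
                       as.character(cohort[[col]][i]))
  }
  check_enum("disorder_class", disorder_class_labels, "disorder_class")
  check_enum("severity_level", sev_codes, "severity_level")
  check_enum("onset_class", onset_classes, "onset_class")
  check_enum("prevalence_provenance", prevalence_provenances,
             "prevalence_provenance")
  check_enum("dbs_status", dbs_statuses, "dbs_status")
  check_enum("performance_class", performance_classes, "performance_class")
  check_enum("treatment_availability", treatment_availability_classes,
             "treatment_availability")
  check_enum("outcomes_level", out_codes, "outcomes_level")

  bad_p <- which(!is.na(cohort$prevalence) &
                   (cohort$prevalence < 0 | cohort$prevalence > 1))
  for (i in bad_p) {
    say("row %d (%s): prevalence %g outside [0, 1]", i,
        cohort$disorder_id[i], cohort$prevalence[i])
  }

  inconsistent_screen <- which(cohort$dbs_status %in% "none" &
                                 !(cohort$performance_class %in%
                                     "insufficient_or_none"))
  for (i in inconsistent_screen) {
    say("row %d (%s): dbs_status 'none' requires performance_class 'insufficient_or_none', got '%s'",
        i, cohort$disorder_id[i], cohort$performance_class[i])
  }
  inconsistent_treat <- which(cohort$treatment_availability %in% "none" &
                                !(cohort$outcomes_level %in% out_zero))
  for (i in inconsistent_treat) {
    say("row %d (%s): treatment_availability 'none' requires the zero-point outcomes level, got '%s'",
        i, cohort$disorder_id[i], cohort$outcomes_level[i])
  }
  v
}
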