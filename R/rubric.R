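#' The default NBS evaluation rubric
#'
#' Constructs the three-pillar rubric used to score candidate disorders for
#' newborn screening panels. The pillars and their point caps are Condition
#' (6), Screening (3) and Treatment (4), for a total score range of 0 to 13
#' in half-point steps. Each pillar holds weighted criteria with discrete
#' ordinal levels:
#'
#' * **Condition** — `severity` (0-2, curated ordinal anchors from "no
#'   documented rapid progression" to "rapidly progressing form, can be fatal
#'   by adolescence"), `onset` (0-2, whether all, some or no forms are
#'   asymptomatic in the first weeks of life), `frequency` (0-2, birth
#'   prevalence bands; see [score_frequency()]).
#' * **Screening** — `screen_availability` (0-2: dried-blood-spot assay in
#'   use in a public programme or CE-marked/FDA-approved; in development;
#'   none), `screen_performance` (0-1: low false-positive rate standalone;
#'   second-tier confirmatory strategy available; insufficient data).
#' * **Treatment** — `treat_availability` (0-1.5: EMA-approved; phase III or
#'   an intervention such as diet/HSCT/BMT; limited intervention; none),
#'   `treat_outcomes` (0-2.5, curated ordinal anchors up to "pre-symptomatic
#'   initiation changes prognosis for all forms").
#'
#' The recommendation threshold (total score at or above which a disorder is
#' proposed for panel inclusion) is a rubric field, default 8.5, so that
#' national programmes can re-threshold without touching the scoring.
#'
#' @param threshold recommendation cut-off in points, in `[0, 13]`.
#' @return An object of class `nbs_rubric`: a named list with fields `name`,
#'   `version`, `threshold`, `total_max` and `pillars`, where each pillar has
#'   `name`, `cap` and a list of `criteria`, each criterion `name`,
#'   `max_points` and a list of `levels` (`code`, `label`, `points`).
#' @examples
#' r <- default_rubric()
#' r$total_max
#' vapply(r$pillars, `[[`, numeric(1), "cap")
#' @seealso [validate_rubric()], [read_rubric()], [write_rubric()]
#' @export
default_rubric <- function(threshold = 8.5) {
  lv <- function(code, label, points) {
    list(code = code, label = label, points = points)
  }
  crit <- function(name, levels) {
    list(name = name,
         max_points = max(vapply(levels, `[[`, numeric(1), "points")),
         levels = levels)
  }
  pillar <- function(name, criteria) {
    list(name = name,
         cap = sum(vapply(criteria, `[[`, numeric(1), "max_points")),
         criteria = criteria)
  }

  severity <- crit("severity", list(
    lv("S0",   "no documented rapid progression or early fatality", 0),
    lv("S0.5", "progressive course, limited early mortality", 0.5),
    lv("S1",   "progressive course with significant morbidity", 1),
    lv("S1.5", "rapidly progressing form present", 1.5),
    lv("S2",   "rapidly progressing form; can be fatal by adolescence", 2)))
  onset <- crit("onset", list(
    lv("all_forms_asymptomatic_first_weeks",
       "all forms asymptomatic for the first few weeks of life", 2),
    lv("some_forms_asymptomatic",
       "some forms asymptomatic in the newborn period", 1),
    lv("symptomatic_at_birth_or_unknown",
       "symptomatic at or soon after birth, or onset unknown", 0)))
  frequency <- crit("frequency", list(
    lv("ge_1_in_50k",   "birth prevalence at or above 1 in 50,000", 2),
    lv("1_in_50k_100k", "between 1 in 50,000 and 1 in 100,000", 1.5),
    lv("1_in_100k_150k", "between 1 in 100,000 and 1 in 150,000", 1),
    lv("1_in_150k_250k", "between 1 in 150,000 and 1 in 250,000", 0.5),
    lv("lt_1_in_250k_or_unknown",
       "below 1 in 250,000, or no estimate available", 0)))
  screen_avail <- crit("screen_availability", list(
    lv("in_use_or_registered",
       "DBS assay in a public NBS programme, or CE-marked/FDA-approved", 2),
    lv("in_development", "DBS assay in development", 1),
    lv("none", "no DBS assay", 0)))
  screen_perf <- crit("screen_performance", list(
    lv("low_fp_standalone", "low false-positive rate by itself", 1),
    lv("second_tier_available",
       "confirmatory second-tier strategy required and available", 0.5),
    lv("insufficient_or_none", "insufficient or no performance data", 0)))
  treat_avail <- crit("treat_availability", list(
    lv("ema_approved", "EMA-approved treatment", 1.5),
    lv("phase3_or_intervention",
       "phase III investigational, or intervention (diet/HSCT/BMT)", 1),
    lv("limited_intervention", "limited treatment intervention", 0.5),
    lv("none", "no treatment strategy", 0)))
  treat_out <- crit("treat_outcomes", list(
    lv("O0",   "no available clinical data", 0),
    lv("O0.5", "minimal clinical data on outcome benefit", 0.5),
    lv("O1",   "outcome benefit for some forms", 1),
    lv("O1.5", "clear outcome benefit, not all forms", 1.5),
    lv("O2",   "pre-symptomatic initiation improves outcomes", 2),
    lv("O2.5",
       "pre-symptomatic initiation changes prognosis for all forms", 2.5)))

  rubric <- structure(list(
    name = "imd-nbs-evaluation",
    version = "1.0",
    threshold = threshold,
    total_max = 13,
    pillars = list(
      pillar("condition", list(severity, onset, frequency)),
      pillar("screening", list(screen_avail, screen_perf)),
      pillar("treatment", list(treat_avail, treat_out)))),
    class = "nbs_rubric")
  stopifnot(length(validate_rubric(rubric)) == 0L)
  rubric
}

#' @export
print.nbs_rubric <- function(x, ...) {
  cat(sprintf("<nbs_rubric> %s v%s (total max %s, threshold %s)\n",
              x$name, x$version, fmt_pts(x$total_max), fmt_pts(x$threshold)))
  for (p in x$pillars) {
    cat(sprintf("  %s (cap %s): %s\n", p$name, fmt_pts(p$cap),
                paste(vapply(p$criteria, function(cr) {
                  sprintf("%s [max %s]", cr$name, fmt_pts(cr$max_points))
                }, character(1)), collapse = ", ")))
  }
  invisible(x)
}

# flat lookup: criterion name -> list(pillar, criterion spec)
rubric_criteria <- function(rubric) {
  out <- list()
  for (p in rubric$pillars) {
    for (cr in p$criteria) {
      out[[cr$name]] <- list(pillar = p$name, criterion = cr)
    }
  }
  out
}

# points for a level code within one criterion; NA if unknown code
level_points <- function(criterion, code) {
  for (l in criterion$levels) {
    if (identical(l$code, code)) return(l$points)
  }
  NA_real_
}

criterion_level_points <- function(criterion) {
  vapply(criterion$levels, `[[`, numeric(1), "points")
}

#' Validate a rubric's structural invariants
#'
#' Checks that every level's points are non-negative multiples of 0.5, level
#' codes are unique within each criterion, each criterion's `max_points`
#' equals the maximum of its level points, each pillar's cap equals the sum
#' of its criteria's `max_points`, `total_max` equals the sum of the caps,
#' and the threshold lies in `[0, total_max]`.
#'
#' @param rubric an `nbs_rubric` (or structurally equivalent list).
#' @return Character vector of human-readable violations; empty if the
#'   rubric is valid. Violations are returned, never raised.
#' @examples
#' validate_rubric(default_rubric())   # character(0)
#' @export
validate_rubric <- function(rubric) {
  v <- character(0)
  say <- function(...) v <<- c(v, sprintf(...))

  if (!is.list(rubric$pillars) || length(rubric$pillars) == 0L) {
    return("rubric has no pillars")
  }
  for (p in rubric$pillars) {
    crit_max <- numeric(0)
    for (cr in p$criteria) {
      pts <- criterion_level_points(cr)
      codes <- vapply(cr$levels, `[[`, character(1), "code")
      bad <- pts < 0
      if (any(bad)) {
        say("pillar '%s' criterion '%s': negative points for level(s) %s",
            p$name, cr$name, paste(codes[bad], collapse = ", "))
      }
      off <- !is_half_step(pts)
      if (any(off)) {
        say("pillar '%s' criterion '%s': points not a multiple of 0.5 for level(s) %s",
            p$name, cr$name, paste(codes[off], collapse = ", "))
      }
      if (anyDuplicated(codes)) {
        say("pillar '%s' criterion '%s': duplicate level code(s) %s",
            p$name, cr$name,
            paste(unique(codes[duplicated(codes)]), collapse = ", "))
      }
      if (half_units(cr$max_points) != max(half_units(pts))) {
        say("pillar '%s' criterion '%s': max_points %s does not equal the maximum level points %s",
            p$name, cr$name, fmt_pts(cr$max_points), fmt_pts(max(pts)))
      }
      crit_max <- c(crit_max, cr$max_points)
    }
    if (half_units(p$cap) != sum(half_units(crit_max))) {
      say("pillar '%s': cap %s does not equal the sum of criterion max_points (%s)",
          p$name, fmt_pts(p$cap), fmt_pts(sum(crit_max)))
    }
  }
  caps <- vapply(rubric$pillars, `[[`, numeric(1), "cap")
  if (half_units(rubric$total_max) != sum(half_units(caps))) {
    say("total_max %s does not equal the sum of pillar caps (%s)",
        fmt_pts(rubric$total_max), fmt_pts(sum(caps)))
  }
  if (!is.numeric(rubric$threshold) ||
      rubric$threshold < 0 || rubric$threshold > rubric$total_max) {
    say("threshold %s outside [0, %s]",
        as.character(rubric$threshold), fmt_pts(rubric$total_max))
  }
  v
}

#' Read and write rubric configuration files
#'
#' A rubric is serialized as a YAML or JSON document with schema
#' `{name, version, threshold, pillars: [{name, cap, criteria: [{name,
#' max_points, levels: [{code, label, points}]}]}]}`. A descriptive
#' JSON-Schema ships at `system.file("extdata", "rubric.schema.json",
#' package = "nbspanel")`. `read_rubric()` validates the parsed rubric with
#' [validate_rubric()] and rejects invalid ones; round-tripping through
#' `write_rubric()` then `read_rubric()` is lossless.
#'
#' @param source path to a `.yaml`/`.yml`/`.json` file, or a literal
#'   YAML/JSON string.
#' @param format serialization format; inferred from the file extension when
#'   omitted, YAML otherwise.
#' @return `read_rubric()` returns an `nbs_rubric`; `write_rubric()` returns
#'   the serialized text invisibly (and writes it to `path` if given).
#' @examples
#' txt <- write_rubric(default_rubric())
#' identical(read_rubric(txt), default_rubric())
#' @export
read_rubric <- function(source, format = NULL) {
  is_file <- length(source) == 1L && !grepl("[\n{]", source) &&
    file.exists(source)
  if (is.null(format)) {
    format <- if (is_file && grepl("\\.json$", source, ignore.case = TRUE)) {
      "json"
    } else if (!is_file && grepl("^\\s*\\{", source)) "json" else "yaml"
  }
  raw <- tryCatch({
    if (format == "json") {
      jsonlite::fromJSON(source, simplifyVector = FALSE)
    } else if (is_file) {
      yaml::read_yaml(source)
    } else {
      yaml::yaml.load(source)
    }
  }, error = function(e) {
    stop("rubric config parse error: ", conditionMessage(e), call. = FALSE)
  })

  for (key in c("name", "version", "threshold", "pillars")) {
    if (is.null(raw[[key]])) {
      stop("rubric config parse error: missing key '", key, "'",
           call. = FALSE)
    }
  }
  rubric <- structure(list(
    name = as.character(raw$name),
    version = as.character(raw$version),
    threshold = as.numeric(raw$threshold),
    total_max = as.numeric(raw$total_max %||%
                             sum(vapply(raw$pillars, function(p) {
                               as.numeric(p$cap)
                             }, numeric(1)))),
    pillars = lapply(raw$pillars, function(p) {
      list(name = as.character(p$name), cap = as.numeric(p$cap),
           criteria = lapply(p$criteria, function(cr) {
             list(name = as.character(cr$name),
                  max_points = as.numeric(cr$max_points),
                  levels = lapply(cr$levels, function(l) {
                    list(code = as.character(l$code),
                         label = as.character(l$label %||% l$code),
                         points = as.numeric(l$points))
                  }))
           }))
    })), class = "nbs_rubric")

  violations <- validate_rubric(rubric)
  if (length(violations)) {
    stop("invalid rubric config:\n", paste("-", violations, collapse = "\n"),
         call. = FALSE)
  }
  rubric
}

#' @rdname read_rubric
#' @param rubric an `nbs_rubric`.
#' @param path optional output file path.
#' @export
write_rubric <- function(rubric, path = NULL, format = NULL) {
  if (is.null(format)) {
    format <- if (!is.null(path) &&
                  grepl("\\.json$", path, ignore.case = TRUE)) {
      "json"
    } else "yaml"
  }
  plain <- unclass(rubric)
  txt <- if (format == "json") {
    as.character(jsonlite::toJSON(plain, auto_unbox = TRUE, pretty = TRUE,
                                  digits = NA))
  } else {
    yaml::as.yaml(plain)
  }
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}
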