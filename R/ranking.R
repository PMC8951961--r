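#' Rank scorecards and flag recommended disorders
#'
#' Orders a score table by descending total, breaking ties by descending
#' Treatment, Screening then Condition pillar sums, and finally by name
#' (ascending, C locale) so that output is fully deterministic. Each entry
#' is flagged `recommended` when its total meets or exceeds the threshold.
#' Re-ranking a ranked cohort is the identity.
#'
#' @param cards score table from [score_cohort()] (a prior `rank` /
#'   `recommended` column is dropped and recomputed).
#' @param threshold recommendation cut-off in points (default 8.5).
#' @return The score table in rank order with `rank` (1..n) and
#'   `recommended` columns, threshold attached as attribute `threshold`.
#' @examples
#' ranked <- rank_scorecards(score_cohort(imd_cohort()))
#' ranked[1:2, c("rank", "name", "total", "recommended")]
#' @export
rank_scorecards <- function(cards, threshold = 8.5) {
  cards <- tibble::as_tibble(cards)
  cards$rank <- NULL
  cards$recommended <- NULL
  if (anyDuplicated(cards$disorder_id)) {
    stop("duplicate disorder_id in scorecards: ",
         paste(unique(cards$disorder_id[duplicated(cards$disorder_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (nrow(cards)) {
    old <- Sys.getlocale("LC_COLLATE")
    on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
    Sys.setlocale("LC_COLLATE", "C")
    ord <- order(-half_units(cards$total), -half_units(cards$treatment_sum),
                 -half_units(cards$screening_sum),
                 -half_units(cards$condition_sum), cards$name)
    cards <- cards[ord, ]
  }
  cards$rank <- seq_len(nrow(cards))
  cards$recommended <- pts_ge(cards$total, threshold)
  attr(cards, "threshold") <- threshold
  class(cards) <- c("ranked_cohort", class(cards))
  cards
}

#' Partition a ranked cohort at its recommendation threshold
#'
#' @param ranked a ranked cohort from [rank_scorecards()].
#' @return List with elements `recommended` and `not_recommended`, tibbles
#'   whose row counts sum to the cohort size.
#' @examples
#' parts <- classify_by_threshold(rank_scorecards(score_cohort(imd_cohort())))
#' vapply(parts, nrow, integer(1))
#' @export
classify_by_threshold <- function(ranked) {
  list(recommended = ranked[ranked$recommended, , drop = FALSE],
       not_recommended = ranked[!ranked$recommended, , drop = FALSE])
}

#' Default total-score bins for cohort summaries
#'
#' The bins group totals the way screening-panel reports usually present
#' them: the near-maximal scores, then half-point pairs down to the
#' threshold, then everything below it. Bins are closed ranges on the
#' half-point grid.
#'
#' @return Data frame with columns `label`, `lo`, `hi`.
#' @export
default_score_bins <- function() {
  data.frame(label = c("12-13", "11-11.5", "10-10.5", "9-9.5", "8.5",
                       "<8.5"),
             lo = c(12, 11, 10, 9, 8.5, 0),
             hi = c(13, 11.5, 10.5, 9.5, 8.5, 8))
}

#' Summarize a ranked cohort
#'
#' Computes the cohort summary statistics: total-score bin counts,
#' per-criterion level counts (how many disorders scored each points value
#' of each criterion), and disorder-class counts stratified by
#' recommendation status.
#'
#' @param ranked a ranked cohort from [rank_scorecards()].
#' @param bins score bins as returned by [default_score_bins()].
#' @param rubric rubric supplying the complete level sets (so zero counts
#'   are reported too).
#' @return An `nbs_summary`: list with `n`, `threshold`,
#'   `recommended_count`, `bin_counts` (named integer vector summing to
#'   `n`), `level_counts` (tibble `criterion`, `points`, `count`) and
#'   `class_counts` (tibble `disorder_class`, `recommended`, `count`,
#'   summing to `n`).
#' @examples
#' summarize_cohort(rank_scorecards(score_cohort(imd_cohort())))
#' @export
summarize_cohort <- function(ranked, bins = default_score_bins(),
                             rubric = default_rubric()) {
  hu <- half_units(ranked$total)
  bin_counts <- vapply(seq_len(nrow(bins)), function(i) {
    sum(hu >= half_units(bins$lo[i]) & hu <= half_units(bins$hi[i]))
  }, integer(1))
  names(bin_counts) <- bins$label

  crits <- rubric_criteria(rubric)
  level_counts <- do.call(rbind, lapply(names(crits), function(nm) {
    pts <- sort(unique(criterion_level_points(crits[[nm]]$criterion)))
    data.frame(criterion = nm, points = pts,
               count = vapply(pts, function(p) {
                 sum(half_units(ranked[[nm]]) == half_units(p))
               }, integer(1)))
  }))

  cls <- factor(ranked$disorder_class, levels = disorder_class_labels)
  rec <- factor(ranked$recommended, levels = c("FALSE", "TRUE"))
  tab <- table(disorder_class = cls, recommended = rec)
  class_counts <- as.data.frame(tab, responseName = "count",
                                stringsAsFactors = FALSE)
  class_counts$recommended <- as.logical(class_counts$recommended)

  structure(list(n = nrow(ranked),
                 threshold = attr(ranked, "threshold"),
                 recommended_count = sum(ranked$recommended),
                 bin_counts = bin_counts,
                 level_counts = tibble::as_tibble(level_counts),
                 class_counts = tibble::as_tibble(class_counts)),
            class = "nbs_summary")
}

#' @export
print.nbs_summary <- function(x, ...) {
  cat(sprintf("<nbs_summary> %d disorders, %d recommended at threshold %s\n",
              x$n, x$recommended_count, fmt_pts(x$threshold)))
  cat("score bins:\n")
  print(x$bin_counts)
  cat("recommended by disorder class:\n")
  rec <- x$class_counts[x$class_counts$recommended, ]
  print(stats::setNames(rec$count, rec$disorder_class))
  invisible(x)
}
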