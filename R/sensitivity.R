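#' Sweep the recommendation threshold
#'
#' Counts how many disorders would be recommended at each threshold of an
#' ascending grid. Counts are non-increasing in the threshold.
#'
#' @param cards score table from [score_cohort()].
#' @param thresholds ascending points values; default 0 to the rubric
#'   maximum in half-point steps.
#' @return Tibble with columns `threshold` and `n_recommended`.
#' @examples
#' threshold_sweep(score_cohort(imd_cohort()), c(0, 8.5, 13.5))
#' @export
threshold_sweep <- function(cards, thresholds = seq(0, 13, by = 0.5)) {
  if (is.unsorted(thresholds, strictly = FALSE)) {
    stop("thresholds must be sorted ascending", call. = FALSE)
  }
  tibble::tibble(
    threshold = as.numeric(thresholds),
    n_recommended = vapply(thresholds, function(t) {
      sum(pts_ge(cards$total, t))
    }, integer(1)))
}

# resolve a pillar or criterion name to the columns it contributes
component_columns <- function(component, rubric) {
  crits <- rubric_criteria(rubric)
  pillars <- vapply(rubric$pillars, `[[`, character(1), "name")
  if (component %in% pillars) {
    names(crits)[vapply(crits, function(x) x$pillar == component,
                        logical(1))]
  } else if (component %in% names(crits)) {
    component
  } else {
    stop(sprintf("unknown rubric component '%s' (pillars: %s; criteria: %s)",
                 component, paste(pillars, collapse = ", "),
                 paste(names(crits), collapse = ", ")), call. = FALSE)
  }
}

#' Ablate a pillar or criterion and measure rank stability
#'
#' Recomputes every disorder's total without one rubric component (a pillar
#' such as `"treatment"` or a single criterion such as `"frequency"`); by
#' additivity the adjusted total is the original total minus the removed
#' component's points. Rank stability is reported as Kendall tau-b
#' concordance between the original and ablated score orderings.
#'
#' @param cards score table from [score_cohort()].
#' @param component pillar or criterion name.
#' @param threshold recommendation cut-off applied to the adjusted totals.
#' @param rubric the scoring rubric.
#' @return An `nbs_ablation`: list with `removed`, `totals` (tibble
#'   `disorder_id`, `original_total`, `removed_points`, `adjusted_total`,
#'   `recommended`), and `rank_concordance`.
#' @examples
#' ab <- criterion_ablation(score_cohort(imd_cohort()), "treatment")
#' ab$rank_concordance
#' @export
criterion_ablation <- function(cards, component, threshold = 8.5,
                               rubric = default_rubric()) {
  cols <- component_columns(component, rubric)
  removed <- rowSums(as.data.frame(cards)[, cols, drop = FALSE])
  adjusted <- cards$total - removed
  totals <- tibble::tibble(disorder_id = cards$disorder_id,
                           original_total = cards$total,
                           removed_points = removed,
                           adjusted_total = adjusted,
                           recommended = pts_ge(adjusted, threshold))
  conc <- rank_concordance(
    stats::setNames(cards$total, cards$disorder_id),
    stats::setNames(adjusted, cards$disorder_id))
  structure(list(removed = component, totals = totals,
                 rank_concordance = conc),
            class = "nbs_ablation")
}

#' @export
print.nbs_ablation <- function(x, ...) {
  cat(sprintf("<nbs_ablation> removed '%s': Kendall tau-b with original ranking = %.3f\n",
              x$removed, x$rank_concordance))
  invisible(x)
}

#' Kendall tau-b concordance between two score orderings
#'
#' Measures agreement between two rankings of the same disorders, given as
#' named numeric vectors of scores (or any rank-equivalent values) keyed by
#' disorder id. Tau-b applies the tie correction, which matters here because
#' rubric totals tie heavily. Two fully tied (constant) vectors are in
#' trivial agreement and return 1.
#'
#' @param order_a,order_b named numeric vectors over the same set of ids.
#' @return Kendall tau-b in `[-1, 1]`.
#' @examples
#' rank_concordance(c(a = 3, b = 2, c = 1), c(a = 1, b = 2, c = 3))
#' @export
rank_concordance <- function(order_a, order_b) {
  if (is.null(names(order_a)) || is.null(names(order_b)) ||
      !setequal(names(order_a), names(order_b)) ||
      length(order_a) != length(order_b)) {
    stop("order_a and order_b must be named vectors over the same id set",
         call. = FALSE)
  }
  order_b <- order_b[names(order_a)]
  const_a <- length(unique(order_a)) <= 1L
  const_b <- length(unique(order_b)) <= 1L
  if (const_a && const_b) return(1)
  if (const_a || const_b) return(NA_real_)
  stats::cor(order_a, order_b, method = "kendall")
}
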