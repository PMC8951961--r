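test_that("threshold sweep counts are non-increasing and match the partition", {
  cards <- score_cohort(imd_cohort())
  sw <- threshold_sweep(cards, c(0, 8.5, 13.5))
  expect_equal(sw$n_recommended, c(48L, 35L, 0L))

  full <- threshold_sweep(cards)
  expect_true(all(diff(full$n_recommended) <= 0))
  expect_equal(threshold_sweep(cards, 13)$n_recommended,
               sum(cards$total == 13))

  expect_equal(threshold_sweep(cards[0, ], c(0, 8.5))$n_recommended,
               c(0L, 0L))
  expect_error(threshold_sweep(cards, c(8.5, 0)), "ascending")
})

test_that("ablation preserves additivity and reports concordance", {
  cards <- score_cohort(imd_cohort())
  ab <- criterion_ablation(cards, "treatment")
  expect_equal(ab$totals$adjusted_total,
               ab$totals$original_total - cards$treatment_sum)
  expect_equal(
    ab$totals$adjusted_total[ab$totals$disorder_id == "cud"], 8.5)

  ab_cond <- criterion_ablation(cards, "condition")
  expect_equal(
    ab_cond$totals$adjusted_total[ab_cond$totals$disorder_id == "mps9"],
    0)

  # single-criterion ablation removes exactly that column
  ab_freq <- criterion_ablation(cards, "frequency")
  expect_equal(ab_freq$totals$adjusted_total,
               cards$total - cards$frequency)

  expect_error(criterion_ablation(cards, "bedside_manner"), "unknown")
})

test_that("ablating a zero-variance component leaves the ranking unchanged", {
  cohort <- generate_cohort(n = 15, seed = 4)
  cohort$dbs_status <- "none"
  cohort$performance_class <- "insufficient_or_none"
  cards <- score_cohort(cohort)
  ab <- criterion_ablation(cards, "screening")
  expect_equal(ab$totals$adjusted_total, cards$total)
  expect_equal(ab$rank_concordance, 1)
})

test_that("rank concordance is Kendall tau-b: agrees with brute-force pair counts", {
  ids <- letters[1:4]
  a <- stats::setNames(c(4, 3, 2, 1), ids)
  b <- stats::setNames(c(3, 4, 2, 1), ids)   # one adjacent swap
  expect_equal(rank_concordance(a, b), brute_force_tau_b(a, b[ids]))
  expect_equal(rank_concordance(a, b), 2 / 3)

  expect_equal(rank_concordance(a, a), 1)
  expect_equal(rank_concordance(a, stats::setNames(rev(unname(a)), ids)),
               -1)

  # heavy-tie cases on cohorts of <= 8 items, ids deliberately shuffled
  withr::with_seed(31, {
    for (k in 1:12) {
      n <- sample(3:8, 1)
      ids <- paste0("d", sample(n))
      x <- stats::setNames(sample(0:3, n, replace = TRUE), ids)
      y <- stats::setNames(sample(0:3, n, replace = TRUE), ids)
      if (length(unique(x)) == 1 || length(unique(y)) == 1) next
      expect_equal(rank_concordance(x, y[sample(ids)]),
                   brute_force_tau_b(x, y[ids]))
    }
  })

  expect_error(rank_concordance(a, stats::setNames(1:4, letters[2:5])),
               "same id set")
  # fully tied vectors are in trivial agreement
  expect_equal(rank_concordance(stats::setNames(rep(1, 3), ids[1:3]),
                                stats::setNames(rep(2, 3), ids[1:3])), 1)
})
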