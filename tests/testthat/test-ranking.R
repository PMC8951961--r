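fixture_ranked <- function(threshold = 8.5) {
  rank_scorecards(score_cohort(imd_cohort()), threshold)
}

test_that("ranking orders by total with the pillar-sum/name tie-break", {
  r <- fixture_ranked()
  expect_equal(r$disorder_id[1:2], c("cud", "scid"))
  expect_equal(r$total[1:2], c(12.5, 12))
  expect_true(all(diff(r$total) <= 0))
  expect_equal(r$rank, 1:48)

  # constructed exact tie falls back to alphabetical name order
  two <- score_cohort(as_evidence_tbl(list(
    make_evidence(disorder_id = "b", name = "Zeta disorder"),
    make_evidence(disorder_id = "a", name = "Alpha disorder"))))
  expect_equal(rank_scorecards(two)$name,
               c("Alpha disorder", "Zeta disorder"))

  one <- rank_scorecards(two[1, ])
  expect_equal(one$rank, 1L)
})

test_that("ranking is a permutation, idempotent, and rejects duplicate ids", {
  r <- fixture_ranked()
  expect_setequal(r$disorder_id, imd_cohort()$disorder_id)
  r2 <- rank_scorecards(r, attr(r, "threshold"))
  expect_equal(as.data.frame(r2), as.data.frame(r))

  cards <- score_cohort(imd_cohort())
  expect_error(rank_scorecards(rbind(cards[1, ], cards[1, ])),
               "duplicate")
})

test_that("threshold classification partitions the cohort", {
  parts <- classify_by_threshold(fixture_ranked())
  expect_equal(nrow(parts$recommended), 35)
  expect_equal(nrow(parts$not_recommended), 13)
  expect_true(all(parts$recommended$total >= 8.5))
  expect_true(all(parts$not_recommended$total < 8.5))

  expect_equal(nrow(classify_by_threshold(fixture_ranked(0))$recommended),
               48)
  expect_equal(
    nrow(classify_by_threshold(fixture_ranked(13.5))$recommended), 0)
})

test_that("recommended sets are nested as the threshold rises", {
  cards <- score_cohort(generate_cohort(n = 30, seed = 9))
  prev <- NULL
  for (t in seq(0, 13, by = 0.5)) {
    rec <- classify_by_threshold(
      rank_scorecards(cards, t))$recommended$disorder_id
    if (!is.null(prev)) expect_true(all(rec %in% prev))
    prev <- rec
  }
})

test_that("cohort summaries reproduce the reference bin and level counts", {
  s <- summarize_cohort(fixture_ranked())
  expect_equal(s$n, 48)
  expect_equal(s$recommended_count, 35)
  expect_equal(unname(s$bin_counts[c("11-11.5", "10-10.5")]), c(7, 14))
  expect_equal(sum(s$bin_counts), 48)

  lc <- s$level_counts
  freq <- lc[lc$criterion == "frequency", ]
  expect_equal(freq$count[match(c(2, 1.5, 1, 0.5, 0), freq$points)],
               c(9, 10, 7, 8, 14))
  ta <- lc[lc$criterion == "treat_availability", ]
  expect_equal(ta$count[ta$points == 1.5], 21)

  cc <- s$class_counts
  expect_equal(sum(cc$count), 48)
  expect_equal(cc$count[cc$disorder_class == "LSD" & cc$recommended], 8)
})

test_that("an empty cohort summarizes to zero counts without error", {
  r <- rank_scorecards(score_cohort(imd_cohort())[0, ], 8.5)
  s <- summarize_cohort(r)
  expect_equal(s$n, 0)
  expect_equal(s$recommended_count, 0)
  expect_true(all(s$bin_counts == 0))
  expect_true(all(s$level_counts$count == 0))
})
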