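test_that("frequency banding maps prevalence to points with closed top band", {
  expect_equal(score_frequency(1 / 50000), 2)       # boundary is inclusive
  expect_equal(score_frequency(1 / 40000), 2)
  expect_equal(score_frequency(1 / 50001), 1.5)
  expect_equal(score_frequency(1 / 100000), 1.5)
  expect_equal(score_frequency(1 / 120000), 1)
  expect_equal(score_frequency(1 / 150000), 1)
  expect_equal(score_frequency(1 / 200000), 0.5)
  expect_equal(score_frequency(1 / 250000), 0.5)
  expect_equal(score_frequency(1 / 300000), 0)
  expect_equal(score_frequency(NA), 0)              # no evidence scores 0
})

test_that("frequency score is non-decreasing in prevalence", {
  p <- sort(c(10^seq(-7, -3, length.out = 60),
              1 / c(50000, 100000, 150000, 250000)))
  s <- score_frequency(p)
  expect_true(all(diff(s) >= 0))
})

test_that("pillar scorers reproduce reference sub-score patterns", {
  # severity pass-through + all-forms onset + top frequency band
  cud_like <- make_evidence(severity_level = "S1.5",
                            onset_class = "all_forms_asymptomatic_first_weeks",
                            prevalence = 1 / 40000)
  expect_equal(unname(score_condition(cud_like)), c(1.5, 2, 2))

  mps9_like <- make_evidence(severity_level = "S0",
                             onset_class = "some_forms_asymptomatic",
                             prevalence = NA_real_)
  expect_equal(unname(score_condition(mps9_like)), c(0, 1, 0))
  expect_equal(unname(score_condition(make_evidence())), c(0, 0, 0))

  expect_equal(unname(score_screening(make_evidence(
    dbs_status = "in_use_or_registered",
    performance_class = "low_fp_standalone"))), c(2, 1))
  expect_equal(unname(score_screening(make_evidence(
    dbs_status = "in_development",
    performance_class = "second_tier_available"))), c(1, 0.5))
  expect_equal(unname(score_screening(make_evidence())), c(0, 0))

  expect_equal(unname(score_treatment(make_evidence(
    treatment_availability = "ema_approved", outcomes_level = "O2.5"))),
    c(1.5, 2.5))
  expect_equal(unname(score_treatment(make_evidence(
    treatment_availability = "phase3_or_intervention",
    outcomes_level = "O0.5"))), c(1, 0.5))
  expect_equal(unname(score_treatment(make_evidence())), c(0, 0))
})

test_that("scorers reject unknown codes and inconsistent treatment evidence", {
  expect_error(score_condition(make_evidence(severity_level = "S9")), "S9")
  expect_error(score_treatment(make_evidence(
    treatment_availability = "none", outcomes_level = "O1")),
    "inconsistent")
})

test_that("score_disorder aggregates to the printed extremes", {
  cud_like <- make_evidence(
    severity_level = "S1.5",
    onset_class = "all_forms_asymptomatic_first_weeks",
    prevalence = 1 / 40000, dbs_status = "in_use_or_registered",
    performance_class = "low_fp_standalone",
    treatment_availability = "ema_approved", outcomes_level = "O2.5")
  card <- score_disorder(cud_like)
  expect_s3_class(card, "scorecard")
  expect_equal(card$total, 12.5)
  expect_equal(unname(card$pillar_sums), c(5.5, 3, 4))

  expect_equal(score_disorder(make_evidence())$total, 0)

  maxed <- make_evidence(
    severity_level = "S2",
    onset_class = "all_forms_asymptomatic_first_weeks",
    prevalence = 1 / 10000, dbs_status = "in_use_or_registered",
    performance_class = "low_fp_standalone",
    treatment_availability = "ema_approved", outcomes_level = "O2.5")
  expect_equal(score_disorder(maxed)$total, 13)
})

test_that("cohort scoring is additive, capped and deterministic", {
  for (seed in c(2, 5)) {
    cohort <- generate_cohort(n = 40, seed = seed)
    cards <- score_cohort(cohort)
    expect_equal(cards$total,
                 cards$condition_sum + cards$screening_sum +
                   cards$treatment_sum)
    expect_true(all(cards$condition_sum <= 6 & cards$screening_sum <= 3 &
                      cards$treatment_sum <= 4))
    expect_true(all(cards$total >= 0 & cards$total <= 13))
    expect_true(all(abs(cards$total * 2 - round(cards$total * 2)) < 1e-9))
    expect_identical(cards, score_cohort(cohort))
  }
  expect_equal(nrow(score_cohort(generate_cohort(n = 0, seed = 1))), 0)
})
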