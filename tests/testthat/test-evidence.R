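test_that("prevalence parses from decimal and 1/N notation consistently", {
  expect_equal(parse_prevalence("1/50000"), 2e-5)
  expect_equal(parse_prevalence("1/50,000"), 2e-5)
  expect_equal(parse_prevalence(c("", NA)), c(NA_real_, NA_real_))
  # both notations agree to machine precision
  p <- parse_prevalence(c("1/120000", "8.3333333333333331e-06"))
  expect_equal(p[1], p[2], tolerance = 1e-12)
  expect_error(parse_prevalence("often"), "unparseable")
})

test_that("evidence tables round-trip through text exactly", {
  cohort <- generate_cohort(n = 12, seed = 11)
  txt <- write_evidence(cohort)
  back <- read_evidence(txt)
  expect_equal(as.data.frame(back), as.data.frame(cohort))

  # unicode names and empty cohorts survive
  one <- as_evidence_tbl(list(make_evidence(name = "α-mannosidosis")))
  expect_equal(read_evidence(write_evidence(one))$name,
               "α-mannosidosis")
  empty <- cohort[0, ]
  expect_equal(nrow(read_evidence(write_evidence(empty))), 0)
})

test_that("read_evidence enforces schema and row-level invariants", {
  cohort <- generate_cohort(n = 2, seed = 3)
  txt <- write_evidence(cohort)
  expect_equal(nrow(read_evidence(txt)), 2)

  # missing column
  broken <- sub("disorder_id", "id", txt)
  expect_error(read_evidence(broken), "disorder_id")
  # unknown enum value, reported with its row
  bad <- cohort
  bad$dbs_status[2] <- "maybe"
  expect_error(read_evidence(write_evidence(bad)), "row 2")
  # cross-field rule: no assay but a performance claim
  bad2 <- as_evidence_tbl(list(make_evidence(
    dbs_status = "none", performance_class = "low_fp_standalone")))
  expect_error(read_evidence(write_evidence(bad2)), "insufficient_or_none")
})

test_that("enumerated fields parse case-insensitively", {
  txt <- write_evidence(as_evidence_tbl(list(make_evidence(
    dbs_status = "in_use_or_registered",
    performance_class = "low_fp_standalone"))))
  txt <- sub("in_use_or_registered", "In_Use_Or_Registered", txt)
  txt <- sub('"other"', '"OTHER"', txt)
  ev <- read_evidence(txt)
  expect_equal(ev$dbs_status, "in_use_or_registered")
  expect_equal(ev$disorder_class, "other")
})

test_that("validate_cohort reports duplicates and invariant breaches", {
  clean <- imd_cohort()
  expect_length(validate_cohort(clean), 0)

  dup <- as_evidence_tbl(list(make_evidence(disorder_id = "a"),
                              make_evidence(disorder_id = "a")))
  expect_match(validate_cohort(dup), "duplicate", all = FALSE)

  incons <- as_evidence_tbl(list(make_evidence(
    treatment_availability = "none", outcomes_level = "O2")))
  expect_match(validate_cohort(incons), "zero-point outcomes",
               all = FALSE)

  bad_p <- as_evidence_tbl(list(make_evidence(prevalence = 1.5)))
  expect_match(validate_cohort(bad_p), "outside", all = FALSE)
})
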