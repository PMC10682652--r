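test_that("objective rule: walk-test branch, biomarker fallback, neither", {
  r <- classify_objective(toy_record(smwt_base = 300, smwt_6m = 335,
                                     ntprobnp_6m = 4000))
  expect_equal(r, list(objective = "improved", reason = "walk_test"))

  r <- classify_objective(toy_record(smwt_base = 300, smwt_6m = 320,
                                     ntprobnp_base = 4000, ntprobnp_6m = 1800))
  expect_equal(r, list(objective = "improved", reason = "biomarker"))

  r <- classify_objective(toy_record(smwt_base = 300, smwt_6m = 310,
                                     ntprobnp_base = 4000, ntprobnp_6m = 3500))
  expect_equal(r, list(objective = "not_improved", reason = "neither"))

  # thresholds are inclusive ("at least")
  expect_equal(classify_objective(toy_record(smwt_base = 300, smwt_6m = 330,
                                             ntprobnp_6m = 9000))$objective,
               "improved")
  expect_equal(classify_objective(toy_record(smwt_base = 300, smwt_6m = 329,
                                             ntprobnp_base = 4000,
                                             ntprobnp_6m = 2000))$objective,
               "improved")
})

test_that("death handling follows the 30-day / 6-month windows", {
  expect_equal(classify_objective(toy_record(death_time = 20,
                                             death_cause = "other")),
               list(objective = "excluded",
                    reason = "death_before_30d_other_excluded"))
  expect_equal(classify_objective(toy_record(death_time = 20,
                                             death_cause = "heart_failure")),
               list(objective = "not_improved", reason = "death_before_30d_hf"))

  # death between 30 days and 6 months: 30-day evaluation carries forward
  r <- classify_objective(toy_record(death_time = 100, death_cause = "other",
                                     smwt_30d = 350, smwt_6m = NA,
                                     ntprobnp_6m = NA))
  expect_equal(r, list(objective = "improved",
                       reason = "death_30d_to_6m_carryforward"))

  r <- classify_objective(toy_record(death_time = 100, death_cause = "other",
                                     smwt_30d = 305, ntprobnp_30d = 3500,
                                     smwt_6m = NA, ntprobnp_6m = NA))
  expect_equal(r$objective, "not_improved")

  # ... unless heart failure intervened
  r <- classify_objective(toy_record(death_time = 100,
                                     death_cause = "heart_failure",
                                     smwt_30d = 350))
  expect_equal(r, list(objective = "not_improved", reason = "death_30d_to_6m_hf"))
  r <- classify_objective(toy_record(death_time = 100, death_cause = "other",
                                     hf_event_after_30d = TRUE, smwt_30d = 350))
  expect_equal(r$objective, "not_improved")

  # deaths after 6 months classify as survivors
  expect_equal(classify_objective(toy_record(death_time = 400,
                                             death_cause = "heart_failure",
                                             smwt_6m = 350))$objective,
               "improved")
})

test_that("a survivor missing both 6-month pairs raises with the missing fields", {
  expect_error(classify_objective(toy_record(smwt_6m = NA, ntprobnp_6m = NA)),
               "smwt_6m.*ntprobnp_6m")
})

test_that("subjective rule: NYHA and/or KCCQ, missing when neither pair exists", {
  expect_equal(classify_subjective(toy_record(nyha_pre = 3, nyha_post = 2,
                                              kccq_pre = NA, kccq_post = NA)),
               "improved")
  expect_equal(classify_subjective(toy_record(nyha_pre = 3, nyha_post = 3,
                                              kccq_pre = 40, kccq_post = 49)),
               "not_improved")
  expect_equal(classify_subjective(toy_record(nyha_pre = NA, nyha_post = NA,
                                              kccq_pre = 40, kccq_post = 55)),
               "improved")
  expect_equal(classify_subjective(toy_record(nyha_pre = 3, nyha_post = 3,
                                              kccq_pre = 40, kccq_post = 50)),
               "improved")               # 10-point gain is inclusive
  expect_equal(classify_subjective(toy_record(nyha_pre = NA, nyha_post = NA,
                                              kccq_pre = NA, kccq_post = NA)),
               "missing")
})

test_that("classification is total and deterministic over randomized records", {
  set.seed(17)
  for (i in 1:300) {
    rec <- toy_record(
      smwt_base = runif(1, 100, 500),
      smwt_6m = runif(1, 80, 600), smwt_30d = runif(1, 80, 600),
      ntprobnp_base = exp(runif(1, 6, 10)),
      ntprobnp_6m = exp(runif(1, 5, 10)), ntprobnp_30d = exp(runif(1, 5, 10)),
      death_time = if (runif(1) < 0.3) runif(1, 1, 700) else NA_real_,
      death_cause = sample(c("heart_failure", "other"), 1),
      hf_event_after_30d = runif(1) < 0.2
    )
    a <- classify_objective(rec)
    b <- classify_objective(rec)
    expect_identical(a, b)
    expect_true(a$objective %in% c("improved", "not_improved", "excluded"))
    expect_identical(a$objective == "excluded",
                     a$reason == "death_before_30d_other_excluded")
  }
})

test_that("raising the walk threshold only demotes patients", {
  set.seed(23)
  for (i in 1:100) {
    rec <- toy_record(smwt_base = 300, smwt_6m = runif(1, 280, 400),
                      ntprobnp_6m = 6000)   # biomarker never rescues
    lo <- classify_objective(rec, walk_gain = 0.10)$objective
    hi <- classify_objective(rec, walk_gain = 0.20)$objective
    expect_false(lo == "not_improved" && hi == "improved")
  }
})

test_that("tabulation excludes the excluded and rounds to one decimal", {
  labels <- data.frame(
    objective = c(rep("improved", 82), rep("not_improved", 20)),
    subjective = c(rep("improved", 93), rep("not_improved", 9)))
  tab <- tabulate_outcomes(labels)
  expect_equal(tab$pct_objective, 80.4)
  expect_equal(tab$pct_subjective, 91.2)
  expect_equal(round(tab$pct_subjective), 91)

  labels2 <- data.frame(objective = c(rep("not_improved", 10), "excluded"))
  tab2 <- tabulate_outcomes(labels2)
  expect_equal(tab2$pct_objective, 0.0)
  expect_equal(tab2$n_analysed, 10)      # excluded never in the denominator
  expect_error(tabulate_outcomes(data.frame(objective = character(0))), "no records")
})
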