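test_that("built-in weight sets carry the published weights and maxima", {
  cv <- score_weights("chads_vasc")
  expect_equal(cv$weights[["heart_failure"]], 1L)
  expect_equal(cv$weights[["stroke_tia"]], 2L)
  expect_equal(cv$weights[["age_ge75"]], 2L)
  expect_equal(cv$weights[["copd"]], 0L)
  expect_equal(max_score(cv), 9L)

  av <- score_weights("a2c2s2_vasc")
  expect_equal(av$weights[["hypertension"]], 0L)
  expect_equal(av$weights[["diabetes"]], 0L)
  expect_equal(av$weights[["heart_failure"]], 2L)
  expect_equal(max_score(av), 8L)

  ha <- score_weights("hatch")
  expect_equal(unname(ha$weights[c("heart_failure", "hypertension",
                                   "age_ge75", "stroke_tia", "copd")]),
               c(2L, 1L, 1L, 2L, 1L))
  expect_equal(max_score(ha), 7L)

  expect_error(score_weights("nope"), "chads_vasc.*a2c2s2_vasc.*hatch")
  expect_error(score_weights("x", weights = c(bogus = 1)), "unknown score component")
})

test_that("snapshot applies onset-threshold and ageing semantics", {
  rec <- make_record(hf_onset = 200L, age_at_index = 64L, followup_end = 400L)
  expect_false(snapshot(rec, 100L)$heart_failure)
  expect_true(snapshot(rec, 200L)$heart_failure)
  # turns 65 during follow-up: 365.25-day years
  expect_false(snapshot(rec, 300L)$age_65_74)
  expect_true(snapshot(rec, 400L)$age_65_74)
  # day 0 equals the baseline flags
  rec2 <- make_record(htn_onset = -10L, dm_onset = 5L)
  s0 <- snapshot(rec2, 0L)
  expect_true(s0$hypertension)
  expect_false(s0$diabetes)
  expect_error(snapshot(rec, 401L), "followup_end")
  expect_error(snapshot(rec, -1L), "followup_end")
})

test_that("hand-scored examples evaluate correctly", {
  none <- make_record(sex = "male", age_at_index = 50L)
  expect_equal(score_snapshot(snapshot(none, 0L), score_weights("chads_vasc")), 0L)

  full <- make_record(sex = "female", age_at_index = 80L, hf_onset = -1L,
                      stroke_onset = -1L, vasc_onset = -1L)
  expect_equal(score_snapshot(snapshot(full, 0L), score_weights("a2c2s2_vasc")), 8L)

  full9 <- make_record(sex = "female", age_at_index = 80L, hf_onset = -1L,
                       htn_onset = -1L, dm_onset = -1L, stroke_onset = -1L,
                       vasc_onset = -1L)
  expect_equal(score_snapshot(snapshot(full9, 0L), score_weights("chads_vasc")), 9L)
})

test_that("trajectories capture incident comorbidity and band crossing", {
  # baseline hypertension, male age 64; gains heart failure day 200 and
  # turns 65 around day 183; window ends day 400
  rec <- make_record(sex = "male", age_at_index = 64L, htn_onset = -30L,
                     hf_onset = 200L, followup_end = 400L)
  cv <- score_trajectory(rec, score_weights("chads_vasc"))
  expect_equal(cv$baseline, 1L)
  expect_equal(cv$follow_up, 3L)
  expect_equal(cv$delta, 2L)
  av <- score_trajectory(rec, score_weights("a2c2s2_vasc"))
  expect_equal(av$baseline, 0L)
  expect_equal(av$follow_up, 3L)
  expect_equal(av$delta, 3L)

  flat <- make_record(followup_end = 100L)
  expect_equal(score_trajectory(flat, score_weights("chads_vasc"))$delta, 0L)
})

test_that("the two systems differ exactly by the reweighting rule, exhaustively", {
  combos <- expand.grid(hf = c(FALSE, TRUE), htn = c(FALSE, TRUE),
                        dm = c(FALSE, TRUE), stroke = c(FALSE, TRUE),
                        vasc = c(FALSE, TRUE), copd = c(FALSE, TRUE),
                        band = 0:2, female = c(FALSE, TRUE))
  ages <- c(50L, 70L, 80L)
  co <- dplyr::bind_rows(purrr::pmap(combos, function(hf, htn, dm, stroke, vasc,
                                                      copd, band, female) {
    make_record(
      sex = if (female) "female" else "male",
      age_at_index = ages[band + 1],
      hf_onset = if (hf) -1L else NA, htn_onset = if (htn) -1L else NA,
      dm_onset = if (dm) -1L else NA, stroke_onset = if (stroke) -1L else NA,
      vasc_onset = if (vasc) -1L else NA, copd_onset = if (copd) -1L else NA,
      followup_end = 1L
    )
  }))
  snap <- snapshot(co, 0L)
  s_cv <- score_snapshot(snap, score_weights("chads_vasc"))
  s_av <- score_snapshot(snap, score_weights("a2c2s2_vasc"))
  expect_equal(s_av - s_cv, as.integer(combos$hf - combos$htn - combos$dm))
  expect_true(all(s_cv >= 0 & s_cv <= 9))
  expect_true(all(s_av >= 0 & s_av <= 8))
})

test_that("scores are monotone in components and delta is non-negative", {
  co <- generate_cohort(small_params(400), seed = 21)
  for (nm in c("chads_vasc", "a2c2s2_vasc", "hatch")) {
    traj <- score_trajectory(co, score_weights(nm))
    expect_true(all(traj$delta >= 0))
    expect_equal(traj$follow_up, traj$baseline + traj$delta)
    expect_true(all(traj$follow_up <= max_score(score_weights(nm))))
  }
  # adding a present component never decreases the score
  base <- make_record()
  with_hf <- make_record(hf_onset = -1L)
  w <- score_weights("chads_vasc")
  expect_gte(score_snapshot(snapshot(with_hf, 0L), w),
             score_snapshot(snapshot(base, 0L), w))
})
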