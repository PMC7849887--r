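test_that("relative risks carry Katz log-method confidence intervals", {
  dat <- tibble::tibble(
    score = rep(c(0L, 1L), each = 100),
    event = c(rep(c(TRUE, FALSE), c(10, 90)), rep(c(TRUE, FALSE), c(20, 80)))
  )
  rt <- risk_table(dat, "score", "event")
  expect_true(rt$reference[1])
  expect_equal(rt$relative_risk[1], 1)
  expect_true(is.na(rt$ci_low[1]))
  expect_equal(rt$relative_risk[2], 2)
  expect_equal(rt$ci_low[2], 0.986, tolerance = 1e-3)
  expect_equal(rt$ci_high[2], 4.055, tolerance = 1e-3)

  # stratum identical to the reference
  same <- tibble::tibble(score = rep(0:1, each = 50),
                         event = rep(rep(c(TRUE, FALSE), c(5, 45)), 2))
  expect_equal(risk_table(same, "score", "event")$relative_risk[2], 1)

  expect_error(risk_table(dplyr::mutate(dat, score = score + 1L),
                          "score", "event"), "reference stratum")
  expect_error(risk_table(dplyr::mutate(dat, event = TRUE), "score", "event"),
               "non-events")
})

test_that("sparse top strata are merged into a top-coded band", {
  dat <- tibble::tibble(
    score = rep(c(0L, 1L, 2L, 3L), c(50, 50, 12, 5)),
    event = rep(c(FALSE, TRUE), length.out = 117)
  )
  rt <- risk_table(dat, "score", "event", min_stratum = 20)
  expect_equal(rt$score_level, c("0", "1", "2+"))
  expect_equal(rt$n_total, c(50L, 50L, 17L))
})

test_that("a zero-event stratum gets the continuity-corrected interval", {
  dat <- tibble::tibble(score = rep(0:1, each = 40),
                        event = c(rep(c(TRUE, FALSE), c(8, 32)),
                                  rep(FALSE, 40)))
  rt <- risk_table(dat, "score", "event", min_stratum = 10)
  expect_true(is.finite(rt$ci_low[2]) && rt$ci_low[2] > 0)
  expect_true(is.finite(rt$ci_high[2]))
})

test_that("in a 1:1 matched cohort the pooled AF risk is one half", {
  co <- generate_cohort(small_params(200), seed = 17)
  traj <- score_trajectory(co, score_weights("chads_vasc"))
  dat <- tibble::tibble(score = traj$delta, af = co$group == "afl_daf")
  rt <- risk_table(dat, "score", "af", min_stratum = 5)
  expect_equal(sum(rt$n_events) / sum(rt$n_total), 0.5)
})

test_that("AUC equals the brute-force pairwise concordance", {
  expect_equal(auc(c(3, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.875)
  expect_equal(auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(auc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)

  withr::local_seed(99)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    scores <- sample(0:8, n, replace = TRUE)
    outcome <- stats::runif(n) < 0.3
    if (!any(outcome) || all(outcome)) next
    expect_equal(auc(scores, outcome)$auc, auc_brute_force(scores, outcome))
  }
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "non-event")
})

test_that("DeLong AUC inference agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(12)
  for (i in 1:10) {
    n <- 150
    outcome <- stats::runif(n) < 0.4
    if (!any(outcome) || all(outcome)) next
    scores <- stats::rnorm(n) + outcome
    ours <- auc(scores, outcome)
    ref <- suppressMessages(pROC::ci.auc(pROC::roc(outcome, scores,
                                                   direction = "<"),
                                         method = "delong"))
    expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-10)
    expect_equal(ours$ci_low, max(0, as.numeric(ref[1])), tolerance = 1e-8)
    expect_equal(ours$ci_high, min(1, as.numeric(ref[3])), tolerance = 1e-8)
  }
})

test_that("paired AUC comparison is antisymmetric with a degenerate self-difference", {
  withr::local_seed(3)
  n <- 200
  outcome <- stats::runif(n) < 0.3
  a <- stats::rnorm(n) + outcome
  b <- stats::rnorm(n) + 0.5 * outcome
  ab <- compare_auc(a, b, outcome)
  ba <- compare_auc(b, a, outcome)
  expect_equal(ab$delta_auc, -ba$delta_auc)
  expect_equal(ab$se, ba$se)
  expect_equal(ab$p_value, ba$p_value)

  self <- compare_auc(a, a, outcome)
  expect_equal(self$delta_auc, 0)
  expect_equal(self$se, 0)
  expect_true(is.na(self$p_value))

  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(pROC::roc(outcome, a, direction = "<"),
                        pROC::roc(outcome, b, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ab$p_value, as.numeric(ref$p.value), tolerance = 1e-8)
})

test_that("score calibration is monotone, bounded, and falls back under separation", {
  outcome <- rep(c(FALSE, TRUE), c(60, 40))
  scores <- c(stats::rnorm(60, 1), stats::rnorm(40, 2))
  p <- score_to_risk(scores, outcome)
  expect_true(all(p > 0 & p < 1))
  expect_true(all(diff(p[order(scores)]) >= -1e-12))

  # constant score: everyone gets the prevalence
  pc <- score_to_risk(rep(2, 100), outcome)
  expect_equal(unique(round(pc, 10)), 0.4)

  # perfectly separated two-level score: empirical rates with 0.5 correction
  sep_scores <- rep(c(0, 1), c(60, 40))
  ps <- score_to_risk(sep_scores, rep(c(FALSE, TRUE), c(60, 40)))
  expect_equal(unique(ps[sep_scores == 0]), 0.5 / 61)
  expect_equal(unique(ps[sep_scores == 1]), 40.5 / 41)
})

test_that("IDI matches the discrimination-slope identity and direct formula", {
  # means: events 0.6 vs 0.5, non-events 0.3 vs 0.35
  p_new <- c(0.7, 0.5, 0.2, 0.4)
  p_old <- c(0.6, 0.4, 0.3, 0.4)
  outcome <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(idi(p_new, p_old, outcome)$idi, 0.15)

  withr::local_seed(44)
  n <- 300
  y <- stats::runif(n) < 0.3
  pn <- stats::runif(n)
  po <- stats::runif(n)
  est <- idi(pn, po, y)$idi
  slope <- function(p) mean(p[y]) - mean(p[!y])
  expect_equal(est, slope(pn) - slope(po), tolerance = 1e-12)
  expect_equal(idi(pn, pn, y)$idi, 0)
  expect_equal(idi(po, pn, y)$idi, -est)
})

test_that("category-free NRI counts net up/down movement", {
  p_old <- rep(0.5, 8)
  p_new <- c(0.6, 0.7, 0.8, 0.4, # events: 3 up, 1 down
             0.6, 0.4, 0.3, 0.2) # non-events: 1 up, 3 down
  outcome <- rep(c(TRUE, FALSE), each = 4)
  expect_equal(nri_continuous(p_new, p_old, outcome)$nri, 1.0)
  expect_equal(nri_continuous(p_old, p_old, outcome)$nri, 0)

  # oracle: direct counting, ties in neither direction
  withr::local_seed(55)
  for (i in 1:20) {
    n <- 80
    y <- stats::runif(n) < 0.4
    pn <- round(stats::runif(n), 1)
    po <- round(stats::runif(n), 1)
    up <- pn > po
    down <- pn < po
    oracle <- (mean(up[y]) - mean(down[y])) + (mean(down[!y]) - mean(up[!y]))
    est <- nri_continuous(pn, po, y)$nri
    expect_equal(est, oracle)
    expect_gte(est, -2)
    expect_lte(est, 2)
  }
})

test_that("the discrimination report favours delta scores when stroke follows the delta", {
  co <- generate_cohort(cohort_params(n_per_group = 2500), seed = 31)
  rep_ <- discrimination_report(co)
  delta_rows <- rep_[grepl("^delta", rep_$model) &
                       grepl("^follow_up", rep_$reference), ]
  expect_equal(nrow(delta_rows), 2L)
  expect_true(all(delta_rows$delta_auc > 0))
  expect_true(all(delta_rows$idi > 0))
  expect_true(all(delta_rows$nri > 0))
  expect_true(all(rep_$auc >= 0 & rep_$auc <= 1))
})
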