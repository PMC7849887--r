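#' Relative risk of an outcome by score stratum
#'
#' Event risk per score level with the 0-score stratum as the reference;
#' relative risks carry Katz log-method 95% confidence intervals,
#' `exp(ln RR +/- 1.96 sqrt(1/a - 1/n_s + 1/c - 1/n_0))`, with a 0.5
#' continuity correction applied to all cells when any event cell is zero.
#' Sparse top strata (fewer than `min_stratum` patients) are merged
#' downward into a top-coded band.
#'
#' @param data a data frame with one row per patient.
#' @param score name of the integer score column.
#' @param outcome name of the logical outcome column.
#' @param min_stratum minimum patients per stratum before top-coding
#'   (default 20).
#' @return a `risk_table` tibble: `score_level`, `n_total`, `n_events`,
#'   `risk`, `relative_risk`, `ci_low`, `ci_high`, `reference`.
#' @export
risk_table <- function(data, score, outcome, min_stratum = 20) {
  s <- data[[score]]
  y <- data[[outcome]]
  stopifnot(is.logical(y) || all(y %in% c(0, 1)))
  y <- as.logical(y)
  if (!any(y) || all(y)) {
    abort("risk_table needs both events and non-events")
  }
  if (!any(s == 0)) abort("reference stratum (score 0) is empty")

  levels <- sort(unique(s))
  n_by <- as.integer(table(factor(s, levels = levels)))
  # top-code: every level above the highest well-filled one merges into a
  # single "k+" band
  non_sparse <- which(n_by >= min_stratum)
  cut_idx <- if (length(non_sparse)) max(non_sparse) else 1L
  if (cut_idx < length(levels)) {
    band_start <- levels[cut_idx + 1L]
    grp <- pmin(s, band_start)
    lab <- function(v) ifelse(v == band_start, paste0(v, "+"),
                              as.character(v))
  } else {
    grp <- s
    lab <- as.character
  }
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(grp = grp, y = y), .data$grp),
    n_total = dplyr::n(), n_events = sum(.data$y), .groups = "drop"
  )
  agg <- dplyr::arrange(agg, .data$grp)
  a0 <- agg$n_events[agg$grp == 0]
  n0 <- agg$n_total[agg$grp == 0]

  rr_ci <- function(a, n_s) {
    if (a == 0 || a0 == 0) {
      a_ <- a + 0.5; c_ <- a0 + 0.5; ns_ <- n_s + 1; n0_ <- n0 + 1
    } else {
      a_ <- a; c_ <- a0; ns_ <- n_s; n0_ <- n0
    }
    rr <- (a_ / ns_) / (c_ / n0_)
    se <- sqrt(1 / a_ - 1 / ns_ + 1 / c_ - 1 / n0_)
    c(rr, exp(log(rr) - 1.96 * se), exp(log(rr) + 1.96 * se))
  }
  est <- t(vapply(seq_len(nrow(agg)),
                  function(i) rr_ci(agg$n_events[i], agg$n_total[i]),
                  numeric(3)))
  out <- tibble::tibble(
    score_level = lab(agg$grp),
    n_total = agg$n_total,
    n_events = agg$n_events,
    risk = agg$n_events / agg$n_total,
    relative_risk = ifelse(agg$grp == 0, 1, est[, 1]),
    ci_low = ifelse(agg$grp == 0, NA_real_, est[, 2]),
    ci_high = ifelse(agg$grp == 0, NA_real_, est[, 3]),
    reference = agg$grp == 0
  )
  class(out) <- c("risk_table", class(out))
  out
}

#' @rdname risk_table
#' @param object a `risk_table`.
#' @param ... ignored.
#' @export
autoplot.risk_table <- function(object, ...) {
  dat <- dplyr::mutate(tibble::as_tibble(object),
                       score_level = factor(.data$score_level,
                                            levels = .data$score_level))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score_level,
                                    y = .data$relative_risk)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "score level", y = "relative risk (95% CI)") +
    ggplot2::theme_minimal()
}

# DeLong placement values: per-event and per-non-event concordance
# fractions, computed with midranks so ties count 0.5.
.placements <- function(scores, outcome) {
  x <- scores[outcome]
  y <- scores[!outcome]
  n_e <- length(x)
  n_n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(n_e)] - r_x) / n_n
  v01 <- 1 - (r_all[n_e + seq_len(n_n)] - r_y) / n_e
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

.check_outcome <- function(outcome) {
  stopifnot(is.logical(outcome) || all(outcome %in% c(0, 1)))
  outcome <- as.logical(outcome)
  if (!any(outcome) || all(outcome)) {
    abort("need at least one event and one non-event")
  }
  outcome
}

#' AUC with a DeLong confidence interval
#'
#' Tie-corrected Mann-Whitney concordance (ties count 0.5) with the DeLong
#' placement-based variance estimator.
#'
#' @param scores numeric scores, higher = more event-like.
#' @param outcome logical (or 0/1) event indicator.
#' @param conf_level confidence level (default 0.95).
#' @return tibble with `auc`, `se`, `ci_low`, `ci_high`.
#' @export
auc <- function(scores, outcome, conf_level = 0.95) {
  outcome <- .check_outcome(outcome)
  pl <- .placements(scores, outcome)
  se <- sqrt(var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    auc = pl$auc, se = se,
    ci_low = max(0, pl$auc - z * se),
    ci_high = min(1, pl$auc + z * se)
  )
}

#' Paired AUC difference (DeLong)
#'
#' Difference `AUC(scores_a) - AUC(scores_b)` for the same patients, with
#' the paired DeLong covariance-adjusted variance, confidence interval and
#' two-sided normal p-value. Antisymmetric in its score arguments.
#'
#' @param scores_a,scores_b numeric score vectors over the same patients.
#' @inheritParams auc
#' @return tibble with `delta_auc`, `se`, `ci_low`, `ci_high`, `p_value`
#'   (`p_value` is `NA` for a degenerate zero-variance comparison).
#' @export
compare_auc <- function(scores_a, scores_b, outcome, conf_level = 0.95) {
  outcome <- .check_outcome(outcome)
  pa <- .placements(scores_a, outcome)
  pb <- .placements(scores_b, outcome)
  n_e <- length(pa$v10)
  n_n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n_e +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n_n
  se <- sqrt(max(v, 0))
  d <- pa$auc - pb$auc
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    delta_auc = d, se = se,
    ci_low = d - z * se, ci_high = d + z * se,
    p_value = if (se == 0) NA_real_ else 2 * pnorm(-abs(d / se))
  )
}

#' Calibrate scores to event probabilities
#'
#' Univariate logistic calibration of the outcome on the score. Under
#' separation the fit falls back to empirical per-level event rates with a
#' 0.5 continuity correction. Probabilities are strictly inside (0, 1) and
#' monotone in the score.
#'
#' @inheritParams auc
#' @return numeric vector of per-patient event probabilities.
#' @export
score_to_risk <- function(scores, outcome) {
  outcome <- .check_outcome(outcome)
  eps <- 1e-12
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(outcome ~ scores, family = binomial(),
        control = glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  p_fit <- as.numeric(fit$fitted.values)
  if (any(p_fit < 1e-8 | p_fit > 1 - 1e-8)) separated <- TRUE
  if (separated || !fit$converged) {
    lev <- sort(unique(scores))
    rate <- vapply(lev, function(l) {
      n <- sum(scores == l)
      (sum(outcome[scores == l]) + 0.5) / (n + 1)
    }, numeric(1))
    p <- rate[match(scores, lev)]
  } else {
    p <- p_fit
  }
  pmin(pmax(p, eps), 1 - eps)
}

#' Integrated discrimination improvement
#'
#' `IDI = (mean p_new - mean p_old | events) - (mean p_new - mean p_old |
#' non-events)`; equivalently the difference in discrimination slopes. The
#' standard asymptotic SE treats events and non-events as independent
#' samples of paired probability differences.
#'
#' @param prob_new,prob_old aligned per-patient event probabilities under
#'   the new and old model.
#' @inheritParams auc
#' @return tibble with `idi`, `se`, `ci_low`, `ci_high`, `p_value`.
#' @export
idi <- function(prob_new, prob_old, outcome, conf_level = 0.95) {
  outcome <- .check_outcome(outcome)
  d <- prob_new - prob_old
  de <- d[outcome]
  dn <- d[!outcome]
  est <- mean(de) - mean(dn)
  se <- sqrt(var(de) / length(de) + var(dn) / length(dn))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    idi = est, se = se,
    ci_low = est - z * se, ci_high = est + z * se,
    p_value = if (se == 0) NA_real_ else 2 * pnorm(-abs(est / se))
  )
}

#' Category-free net reclassification improvement
#'
#' `NRI = [P(up | event) - P(down | event)] + [P(down | non-event) -
#' P(up | non-event)]` where up/down is any increase/decrease of the
#' predicted probability (ties count in neither direction). The estimate
#' lies in [-2, 2]; SE by the continuous-NRI asymptotic formula.
#'
#' @inheritParams idi
#' @return tibble with `nri`, `se`, `ci_low`, `ci_high`, `p_value`.
#' @export
nri_continuous <- function(prob_new, prob_old, outcome, conf_level = 0.95) {
  outcome <- .check_outcome(outcome)
  d <- prob_new - prob_old
  n_e <- sum(outcome)
  n_n <- sum(!outcome)
  up_e <- mean(d[outcome] > 0)
  down_e <- mean(d[outcome] < 0)
  up_n <- mean(d[!outcome] > 0)
  down_n <- mean(d[!outcome] < 0)
  est <- (up_e - down_e) + (down_n - up_n)
  v <- (up_e + down_e - (up_e - down_e)^2) / n_e +
    (up_n + down_n - (down_n - up_n)^2) / n_n
  se <- sqrt(max(v, 0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    nri = est, se = se,
    ci_low = est - z * se, ci_high = est + z * se,
    p_value = if (se == 0) NA_real_ else 2 * pnorm(-abs(est / se))
  )
}

#' Compare two score variants for discriminating an outcome
#'
#' One row of a discrimination report: AUCs of the two variants, the paired
#' DeLong AUC difference, and IDI / category-free NRI computed on
#' probabilities from [score_to_risk()].
#'
#' @param scores_new,scores_old aligned score vectors.
#' @inheritParams auc
#' @param label_new,label_old labels carried into the output.
#' @return a one-row tibble.
#' @export
compare_scores <- function(scores_new, scores_old, outcome,
                           label_new = "new", label_old = "old") {
  outcome <- .check_outcome(outcome)
  a_new <- auc(scores_new, outcome)
  a_old <- auc(scores_old, outcome)
  da <- compare_auc(scores_new, scores_old, outcome)
  p_new <- score_to_risk(scores_new, outcome)
  p_old <- score_to_risk(scores_old, outcome)
  i <- idi(p_new, p_old, outcome)
  r <- nri_continuous(p_new, p_old, outcome)
  tibble::tibble(
    model = label_new, reference = label_old,
    auc = a_new$auc, auc_ci_low = a_new$ci_low, auc_ci_high = a_new$ci_high,
    auc_ref = a_old$auc, auc_ref_ci_low = a_old$ci_low,
    auc_ref_ci_high = a_old$ci_high,
    delta_auc = da$delta_auc, delta_auc_ci_low = da$ci_low,
    delta_auc_ci_high = da$ci_high, delta_auc_p = da$p_value,
    idi = i$idi, idi_ci_low = i$ci_low, idi_ci_high = i$ci_high,
    idi_p = i$p_value,
    nri = r$nri, nri_ci_low = r$ci_low, nri_ci_high = r$ci_high,
    nri_p = r$p_value
  )
}

#' Discrimination report for dynamic scores
#'
#' Builds the four standard comparisons for an outcome: delta vs follow-up
#' score within each scoring system, and the second system vs the first at
#' each timepoint.
#'
#' @param cohort a cohort tibble.
#' @param weights list of exactly two [score_weights()] objects (the
#'   reference system first).
#' @param outcome name of the outcome column interpreted as
#'   event-day-present (default `"stroke_day"`), or a logical vector.
#' @return a tibble with one row per comparison.
#' @export
discrimination_report <- function(cohort,
                                  weights = list(score_weights("chads_vasc"),
                                                 score_weights("a2c2s2_vasc")),
                                  outcome = "stroke_day") {
  stopifnot(length(weights) == 2)
  y <- if (is.character(outcome)) !is.na(cohort[[outcome]]) else outcome
  y <- .check_outcome(y)
  traj <- score_trajectory(cohort, weights)
  wide <- tidyr::pivot_wider(traj, id_cols = "patient_id",
                             names_from = "score_name",
                             values_from = c("follow_up", "delta"))
  wide <- wide[match(cohort$patient_id, wide$patient_id), ]
  n1 <- weights[[1]]$name
  n2 <- weights[[2]]$name
  fu1 <- wide[[paste0("follow_up_", n1)]]
  fu2 <- wide[[paste0("follow_up_", n2)]]
  de1 <- wide[[paste0("delta_", n1)]]
  de2 <- wide[[paste0("delta_", n2)]]
  dplyr::bind_rows(
    compare_scores(de1, fu1, y, paste0("delta_", n1), paste0("follow_up_", n1)),
    compare_scores(de2, fu2, y, paste0("delta_", n2), paste0("follow_up_", n2)),
    compare_scores(fu2, fu1, y, paste0("follow_up_", n2),
                   paste0("follow_up_", n1)),
    compare_scores(de2, de1, y, paste0("delta_", n2), paste0("delta_", n1))
  )
}
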