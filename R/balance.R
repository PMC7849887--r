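#' Standardized differences
#'
#' Pooled two-group forms: for a binary variable with proportions `p_a`,
#' `p_b`, `(p_a - p_b) / sqrt((p_a (1 - p_a) + p_b (1 - p_b)) / 2)`; for a
#' continuous variable, `(m_a - m_b) / sqrt((sd_a^2 + sd_b^2) / 2)`. Both
#' are signed (group a minus group b) and return 0 when both the numerator
#' and the pooled variance vanish, and a signed infinity sentinel when the
#' groups are constant but unequal.
#'
#' @param x_a,n_a,x_b,n_b event counts and totals in the two groups.
#' @return signed standardized difference.
#' @export
std_binary <- function(x_a, n_a, x_b, n_b) {
  stopifnot(n_a >= 1, n_b >= 1, x_a >= 0, x_b >= 0, x_a <= n_a, x_b <= n_b)
  p_a <- x_a / n_a
  p_b <- x_b / n_b
  denom <- sqrt((p_a * (1 - p_a) + p_b * (1 - p_b)) / 2)
  dplyr::if_else(denom == 0,
                 dplyr::if_else(p_a == p_b, 0, sign(p_a - p_b) * Inf),
                 (p_a - p_b) / denom)
}

#' @rdname std_binary
#' @param mean_a,sd_a,mean_b,sd_b group means and standard deviations.
#' @export
std_continuous <- function(mean_a, sd_a, mean_b, sd_b) {
  stopifnot(all(sd_a >= 0), all(sd_b >= 0))
  denom <- sqrt((sd_a^2 + sd_b^2) / 2)
  dplyr::if_else(denom == 0,
                 dplyr::if_else(mean_a == mean_b, 0,
                                sign(mean_a - mean_b) * Inf),
                 (mean_a - mean_b) / denom)
}

#' Classify a standardized difference
#'
#' `|std| < 0.1` is negligible, `0.1 <= |std| <= 0.2` moderate, and
#' `|std| > 0.2` substantial (infinite sentinels are substantial).
#'
#' @param std numeric vector of signed standardized differences.
#' @return character vector.
#' @export
classify_std <- function(std) {
  a <- abs(std)
  dplyr::case_when(
    a < 0.1 ~ "negligible",
    a <= 0.2 ~ "moderate",
    TRUE ~ "substantial"
  )
}

#' Two-group balance table
#'
#' One row per variable and timepoint comparing `solitary_afl` (group a)
#' against `afl_daf` (group b). Comorbidity components are binary at every
#' timepoint: the baseline flag, presence at the end of follow-up, and the
#' delta indicator (present at follow-up and absent at baseline). `female`
#' and the age bands are baseline/follow-up only. Scoring systems passed via
#' `weights` contribute continuous rows (mean and SD of the per-patient
#' baseline, follow-up and delta scores).
#'
#' @param cohort a cohort tibble containing both groups.
#' @param variables variables to tabulate; defaults to female, the age
#'   bands, the six comorbidity components and any `weights`.
#' @param timepoints subset of `c("baseline", "follow_up", "delta")`.
#' @param weights a [score_weights()] object or list of them, for score
#'   rows.
#' @return a tibble: `variable`, `timepoint`, `type`, `n_a`, `stat_a`,
#'   `sd_a`, `n_b`, `stat_b`, `sd_b`, `std`, `category`. For binary rows
#'   `stat_*` is the proportion (and `sd_*` is `NA`).
#' @export
balance_table <- function(cohort,
                          variables = NULL,
                          timepoints = c("baseline", "follow_up", "delta"),
                          weights = list()) {
  if (inherits(weights, "score_weights")) weights <- list(weights)
  timepoints <- match.arg(timepoints, several.ok = TRUE)
  score_names <- vapply(weights, function(w) w$name, character(1))
  if (is.null(variables)) {
    variables <- c("female", "age_65_74", "age_ge75", names(.components),
                   score_names)
  }
  known <- c("female", "age_65_74", "age_ge75", names(.components),
             score_names)
  bad <- setdiff(variables, known)
  if (length(bad)) {
    abort(sprintf("unknown balance variable(s): %s",
                  paste(bad, collapse = ", ")))
  }

  a <- cohort$group == "solitary_afl"
  b <- cohort$group == "afl_daf"
  if (!any(a) || !any(b)) abort("balance_table needs both groups")
  base <- snapshot(cohort, 0L)
  fu <- snapshot(cohort, cohort$followup_end)

  bin_row <- function(variable, timepoint, flag) {
    std <- std_binary(sum(flag[a]), sum(a), sum(flag[b]), sum(b))
    tibble::tibble(
      variable = variable, timepoint = timepoint, type = "binary",
      n_a = sum(a), stat_a = mean(flag[a]), sd_a = NA_real_,
      n_b = sum(b), stat_b = mean(flag[b]), sd_b = NA_real_,
      std = std, category = classify_std(std)
    )
  }
  cont_row <- function(variable, timepoint, value) {
    std <- std_continuous(mean(value[a]), sd(value[a]),
                          mean(value[b]), sd(value[b]))
    tibble::tibble(
      variable = variable, timepoint = timepoint, type = "continuous",
      n_a = sum(a), stat_a = mean(value[a]), sd_a = sd(value[a]),
      n_b = sum(b), stat_b = mean(value[b]), sd_b = sd(value[b]),
      std = std, category = classify_std(std)
    )
  }

  rows <- list()
  binary_vars <- intersect(variables,
                           c("female", "age_65_74", "age_ge75",
                             names(.components)))
  for (v in binary_vars) {
    tps <- timepoints
    # sex never changes; age bands have no new-onset indicator
    if (v %in% c("female", "age_65_74", "age_ge75")) {
      tps <- setdiff(tps, "delta")
      if (v == "female") tps <- setdiff(tps, "follow_up")
    }
    for (tp in tps) {
      flag <- switch(tp,
                     baseline = base[[v]],
                     follow_up = fu[[v]],
                     delta = fu[[v]] & !base[[v]])
      rows[[length(rows) + 1L]] <- bin_row(v, tp, flag)
    }
  }
  for (w in weights) {
    if (!w$name %in% variables) next
    traj <- score_trajectory(cohort, w)
    for (tp in timepoints) {
      value <- switch(tp, baseline = traj$baseline,
                      follow_up = traj$follow_up, delta = traj$delta)
      rows[[length(rows) + 1L]] <- cont_row(w$name, tp, value)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("balance_table", class(out))
  out
}

#' Derive a reweighted scoring system from delta balance
#'
#' Applies the reweighting rule to the delta (new-onset) rows of a balance
#' table: a comorbidity whose incident-rate group difference is substantial
#' gets weight 2, moderate gets 1, negligible gets 0. Sex and age-band
#' weights are inherited from the base system unchanged; COPD is not a
#' component of the derived score.
#'
#' @param balance a [balance_table()] (must contain delta rows for heart
#'   failure, hypertension, diabetes, stroke/TIA and vascular disease).
#' @param base the system supplying sex/age weights (default CHA2DS2-VASc).
#' @param name name of the derived system.
#' @return a [score_weights()] object.
#' @export
derive_weights <- function(balance, base = score_weights("chads_vasc"),
                           name = "derived") {
  comps <- c("heart_failure", "hypertension", "diabetes", "stroke_tia",
             "vascular_disease")
  rows <- balance[balance$timepoint == "delta" & balance$variable %in% comps, ]
  missing <- setdiff(comps, rows$variable)
  if (length(missing)) {
    abort(sprintf("balance table lacks delta rows for: %s",
                  paste(missing, collapse = ", ")))
  }
  cat_w <- c(substantial = 2L, moderate = 1L, negligible = 0L)
  w <- setNames(cat_w[rows$category[match(comps, rows$variable)]], comps)
  score_weights(name, weights = c(
    female = base$weights[["female"]],
    age_65_74 = base$weights[["age_65_74"]],
    age_ge75 = base$weights[["age_ge75"]],
    w, copd = 0L
  ))
}

#' Love plot of a balance table
#'
#' Absolute standardized differences by variable and timepoint, with the
#' 0.1 (negligible) and 0.2 (substantial) thresholds marked.
#'
#' @param object a [balance_table()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.balance_table <- function(object, ...) {
  dat <- dplyr::mutate(tibble::as_tibble(object),
                       abs_std = pmin(abs(.data$std), 2))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$abs_std, y = .data$variable,
                                    colour = .data$timepoint)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = c(0.1, 0.2), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "|standardized difference|", y = NULL,
                  colour = "timepoint") +
    ggplot2::theme_minimal()
}
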