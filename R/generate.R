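#' Parameters of the synthetic claims-style cohort generator
#'
#' Defaults emulate a 1:1 matched atrial-flutter cohort: the two groups share
#' the baseline distribution of score components (matched columns of the
#' source tables) but differ in incident comorbidity rates during follow-up
#' (heart failure 9.3% vs 22.1%, stroke/TIA 4.9% vs 12.7%, vascular disease
#' 11.7% vs 17.5%, hypertension 9.2% vs 10.8%, diabetes 2.6% vs 2.4%).
#' Follow-up durations follow a log-normal truncated at 1095 days with
#' median 0.47 and mean 0.81 years; post-index ischaemic stroke is drawn
#' from a logistic model on the delta CHA2DS2-VASc score so that, by
#' construction, score change carries the stroke signal.
#'
#' Incident probabilities are fractions of the whole group (as cumulative
#' incidence tables report them). The generator conditions on these margins:
#' it draws the expected number of new-onset cases per group and component
#' (rounded) and assigns them uniformly at random among patients free of the
#' component at baseline, so the incidence contrast between groups is a
#' structural property of every generated cohort rather than a large-sample
#' limit.
#'
#' @param n_per_group patients per group (default 4101).
#' @param baseline_prevalence named list (`solitary_afl`, `afl_daf`) of named
#'   numeric vectors over the six comorbidity components.
#' @param incident_prob same shape; probability of new onset during
#'   follow-up as a fraction of the group.
#' @param female_prob,age_band_probs per-group sex and age-band (<65, 65-74,
#'   >=75) distributions; `age_band_probs` must sum to 1.
#' @param age_band_range integer matrix 3x2 of inclusive age ranges sampled
#'   uniformly within each band.
#' @param followup list with `median_years`, `mean_years`, `cap_days`.
#' @param stroke_model list with `intercept` and `slope`: per-patient stroke
#'   probability is `plogis(intercept + slope * delta)` with delta the
#'   CHA2DS2-VASc score change over follow-up.
#' @param seed default seed used by [generate_cohort()] when none is given.
#' @return a `cohort_params` list.
#' @export
cohort_params <- function(n_per_group = 4101,
                          baseline_prevalence = list(
                            solitary_afl = c(
                              heart_failure = 0.120, hypertension = 0.581,
                              diabetes = 0.188, stroke_tia = 0.129,
                              vascular_disease = 0.404, copd = 0.174
                            ),
                            afl_daf = c(
                              heart_failure = 0.127, hypertension = 0.581,
                              diabetes = 0.165, stroke_tia = 0.133,
                              vascular_disease = 0.412, copd = 0.194
                            )
                          ),
                          incident_prob = list(
                            solitary_afl = c(
                              heart_failure = 0.093, hypertension = 0.092,
                              diabetes = 0.026, stroke_tia = 0.049,
                              vascular_disease = 0.117, copd = 0
                            ),
                            afl_daf = c(
                              heart_failure = 0.221, hypertension = 0.108,
                              diabetes = 0.024, stroke_tia = 0.127,
                              vascular_disease = 0.175, copd = 0
                            )
                          ),
                          female_prob = list(solitary_afl = 0.383,
                                             afl_daf = 0.383),
                          age_band_probs = list(
                            solitary_afl = c(1212, 1201, 1688) / 4101,
                            afl_daf = c(1212, 1201, 1688) / 4101
                          ),
                          age_band_range = rbind(c(45L, 64L), c(65L, 74L),
                                                 c(75L, 94L)),
                          followup = list(median_years = 0.47,
                                          mean_years = 0.81,
                                          cap_days = 1095L),
                          stroke_model = list(intercept = -3, slope = 0.5),
                          seed = 1L) {
  params <- list(
    n_per_group = n_per_group,
    baseline_prevalence = baseline_prevalence,
    incident_prob = incident_prob,
    female_prob = female_prob,
    age_band_probs = age_band_probs,
    age_band_range = age_band_range,
    followup = followup,
    stroke_model = stroke_model,
    seed = seed
  )
  errs <- validate_cohort_params(params)
  if (length(errs)) abort(paste(errs, collapse = "\n"))
  structure(params, class = "cohort_params")
}

validate_cohort_params <- function(p) {
  errs <- character()
  chk_prob <- function(x, what) {
    if (any(!is.finite(unlist(x)) | unlist(x) < 0 | unlist(x) > 1)) {
      sprintf("%s: probabilities must be in [0, 1]", what)
    } else character()
  }
  if (!is.numeric(p$n_per_group) || length(p$n_per_group) != 1 ||
      p$n_per_group < 0 || p$n_per_group != round(p$n_per_group)) {
    errs <- c(errs, "n_per_group: must be a non-negative integer")
  }
  for (g in .groups) {
    for (fld in c("baseline_prevalence", "incident_prob")) {
      v <- p[[fld]][[g]]
      if (is.null(v) || !all(names(.components) %in% names(v))) {
        errs <- c(errs, sprintf("%s$%s: must name all six components", fld, g))
      } else {
        errs <- c(errs, chk_prob(v, sprintf("%s$%s", fld, g)))
      }
    }
    errs <- c(errs, chk_prob(p$female_prob[[g]], sprintf("female_prob$%s", g)))
    ab <- p$age_band_probs[[g]]
    if (length(ab) != 3 || abs(sum(ab) - 1) > 1e-9 || any(ab < 0)) {
      errs <- c(errs, sprintf(
        "age_band_probs$%s: must be 3 non-negative values summing to 1", g))
    }
  }
  if (!is.numeric(p$stroke_model$intercept) ||
      !is.numeric(p$stroke_model$slope)) {
    errs <- c(errs, "stroke_model: intercept and slope must be numeric")
  }
  errs
}

#' Solve a truncated log-normal for the follow-up durations
#'
#' Finds `meanlog`/`sdlog` such that the log-normal truncated at `cap_days`
#' has the requested median and mean.
#'
#' @param median_days,mean_days target summaries of the truncated law.
#' @param cap_days truncation point (default 1095).
#' @return list with `meanlog`, `sdlog`, `cap_days`.
#' @export
fit_followup_lognormal <- function(median_days, mean_days, cap_days = 1095) {
  obj <- function(par) {
    mu <- par[1]
    s <- exp(par[2])
    fc <- pnorm((log(cap_days) - mu) / s)
    tmed <- exp(mu + s * qnorm(0.5 * fc))
    tmean <- exp(mu + s^2 / 2) * pnorm((log(cap_days) - mu - s^2) / s) / fc
    (tmed - median_days)^2 + (tmean - mean_days)^2
  }
  fit <- stats::optim(c(log(median_days), 0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 10000))
  if (fit$value > 1e-6) {
    abort("fit_followup_lognormal: could not match the requested summaries")
  }
  list(meanlog = fit$par[1], sdlog = exp(fit$par[2]), cap_days = cap_days)
}

.sample_followup <- function(n, lnorm) {
  u <- runif(n) * plnorm(lnorm$cap_days, lnorm$meanlog, lnorm$sdlog)
  d <- as.integer(ceiling(qlnorm(u, lnorm$meanlog, lnorm$sdlog)))
  pmin(pmax(d, 1L), as.integer(lnorm$cap_days))
}

#' Generate a synthetic atrial-flutter cohort
#'
#' Draws `2 * n_per_group` patient records (see [cohort_params()] for the
#' emulated structure). Solitary-flutter patients are paired 1:1 with
#' `afl_daf` patients and inherit the counterpart's fibrillation date as
#' follow-up end via [assign_counterpart_followup()]. Identical seeds give
#' identical cohorts.
#'
#' @param params a [cohort_params()] object.
#' @param seed integer seed (defaults to `params$seed`).
#' @return a cohort tibble (see [cohort]).
#' @export
generate_cohort <- function(params = cohort_params(), seed = params$seed) {
  stopifnot(inherits(params, "cohort_params"))
  n <- as.integer(params$n_per_group)
  if (n == 0) {
    empty <- make_empty_cohort()
    return(empty)
  }
  withr::local_seed(seed)
  lnorm <- fit_followup_lognormal(
    params$followup$median_years * 365.25,
    params$followup$mean_years * 365.25,
    params$followup$cap_days
  )

  draw_group <- function(group, ids) {
    band <- sample.int(3L, n, replace = TRUE,
                       prob = params$age_band_probs[[group]])
    lo <- params$age_band_range[band, 1]
    hi <- params$age_band_range[band, 2]
    age <- lo + as.integer(floor(runif(n) * (hi - lo + 1)))
    rec <- tibble::tibble(
      patient_id = ids,
      sex = ifelse(runif(n) < params$female_prob[[group]], "female", "male"),
      age_at_index = age,
      group = group
    )
    for (comp in names(.components)) {
      p <- params$baseline_prevalence[[group]][[comp]]
      present <- runif(n) < p
      onset <- rep(NA_integer_, n)
      onset[present] <- -as.integer(floor(runif(sum(present)) * 1826))
      rec[[.components[[comp]]]] <- onset
    }
    rec
  }

  daf <- draw_group("afl_daf", sprintf("D%06d", seq_len(n)))
  sol <- draw_group("solitary_afl", sprintf("S%06d", seq_len(n)))
  daf$followup_end <- .sample_followup(n, lnorm)
  daf$af_day <- daf$followup_end
  sol$followup_end <- NA_integer_
  sol$af_day <- NA_integer_
  daf$stroke_day <- NA_integer_
  sol$stroke_day <- NA_integer_
  daf$prior_af <- sol$prior_af <- FALSE
  daf$ablation <- sol$ablation <- FALSE
  daf$died <- sol$died <- FALSE
  cohort <- dplyr::bind_rows(sol, daf)[, .cohort_cols]

  pairs <- tibble::tibble(solitary_id = sol$patient_id,
                          afl_daf_id = daf$patient_id)
  cohort <- assign_counterpart_followup(cohort, pairs)

  # incident comorbidities: the expected number of new-onset cases per
  # group/component (margin-conditioned, so the cohort reproduces the
  # target incidence structure by construction), assigned uniformly at
  # random among patients free of the component at baseline, with onset
  # timing uniform over the follow-up window
  for (g in .groups) {
    in_g <- cohort$group == g
    for (comp in names(.components)) {
      col <- .components[[comp]]
      p_inc <- params$incident_prob[[g]][[comp]]
      if (p_inc <= 0) next
      at_risk <- which(in_g & is.na(cohort[[col]]))
      m <- min(length(at_risk), as.integer(round(p_inc * sum(in_g))))
      gains <- sample(at_risk, m)
      fu <- cohort$followup_end[gains]
      cohort[[col]][gains] <- 1L + as.integer(floor(runif(length(gains)) * fu))
    }
  }

  # stroke outcome driven by the delta CHA2DS2-VASc score
  traj <- score_trajectory(cohort, score_weights("chads_vasc"))
  p_stroke <- plogis(params$stroke_model$intercept +
                       params$stroke_model$slope * traj$delta)
  hit <- runif(nrow(cohort)) < p_stroke
  fu <- cohort$followup_end[hit]
  cohort$stroke_day[hit] <- 1L + as.integer(floor(runif(sum(hit)) * fu))

  cohort
}
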