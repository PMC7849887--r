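#' Scoring systems
#'
#' A weight set maps the nine score components (female sex, age 65-74,
#' age >= 75, and the six comorbidity flags) to non-negative integer
#' weights. Built-in systems:
#'
#' * `chads_vasc` — CHA2DS2-VASc: CHF 1, hypertension 1, age >=75 2,
#'   diabetes 1, stroke/TIA 2, vascular disease 1, age 65-74 1, female 1
#'   (maximum 9).
#' * `a2c2s2_vasc` — the reweighted variant: age >=75 2, CHF 2, stroke/TIA
#'   2, vascular disease 1, age 65-74 1, female 1; hypertension and diabetes
#'   dropped (maximum 8).
#' * `hatch` — HF 2, hypertension 1, age >=75 1, stroke/TIA 2, COPD 1
#'   (maximum 7).
#'
#' @param name one of `"chads_vasc"`, `"a2c2s2_vasc"`, `"hatch"`, or any
#'   label when `weights` is supplied.
#' @param weights optional named integer vector over (a subset of) the nine
#'   components, for user-defined systems; unnamed components get weight 0.
#' @return a `score_weights` object.
#' @export
score_weights <- function(name, weights = NULL) {
  builtin <- list(
    chads_vasc = c(female = 1, age_65_74 = 1, age_ge75 = 2, heart_failure = 1,
                   hypertension = 1, diabetes = 1, stroke_tia = 2,
                   vascular_disease = 1, copd = 0),
    a2c2s2_vasc = c(female = 1, age_65_74 = 1, age_ge75 = 2, heart_failure = 2,
                    hypertension = 0, diabetes = 0, stroke_tia = 2,
                    vascular_disease = 1, copd = 0),
    hatch = c(female = 0, age_65_74 = 0, age_ge75 = 1, heart_failure = 2,
              hypertension = 1, diabetes = 0, stroke_tia = 2,
              vascular_disease = 0, copd = 1)
  )
  if (is.null(weights)) {
    if (!name %in% names(builtin)) {
      abort(sprintf("unknown scoring system '%s'; valid names: %s",
                    name, paste(names(builtin), collapse = ", ")))
    }
    weights <- builtin[[name]]
  } else {
    bad <- setdiff(names(weights), .score_components)
    if (length(bad)) {
      abort(sprintf("unknown score component(s): %s",
                    paste(bad, collapse = ", ")))
    }
    if (any(weights < 0 | weights != round(weights))) {
      abort("weights must be non-negative integers")
    }
    full <- setNames(rep(0L, length(.score_components)), .score_components)
    full[names(weights)] <- as.integer(weights)
    weights <- full
  }
  structure(list(name = name,
                 weights = as.integer(weights[.score_components]) |>
                   setNames(.score_components)),
            class = "score_weights")
}

#' @export
print.score_weights <- function(x, ...) {
  cat(sprintf("<score_weights> %s (max %d)\n", x$name, max_score(x)))
  w <- x$weights[x$weights > 0]
  cat(paste(sprintf("  %s: %d", names(w), w), collapse = "\n"), "\n")
  invisible(x)
}

#' Maximum attainable score of a weight set
#'
#' The age bands are mutually exclusive, so only the larger band weight can
#' contribute.
#'
#' @param weights a [score_weights()] object.
#' @return integer.
#' @export
max_score <- function(weights) {
  w <- weights$weights
  as.integer(w[["female"]] + max(w[["age_65_74"]], w[["age_ge75"]]) +
               sum(w[names(.components)]))
}

#' Component presence and age band at a given day
#'
#' A component is present at day `t` iff its onset day is `<= t` (onsets are
#' permanent); age at day `t` is `age_at_index + floor(t / 365.25)`, with
#' band boundaries at the 65th and 75th birthdays inclusive.
#'
#' @param cohort a cohort tibble.
#' @param day integer day, scalar or one per row; must lie in
#'   `[0, followup_end]`.
#' @return tibble of logical columns: `female`, `age_65_74`, `age_ge75`, and
#'   the six comorbidity components.
#' @export
snapshot <- function(cohort, day) {
  day <- as.integer(day)
  if (length(day) == 1) day <- rep(day, nrow(cohort))
  if (length(day) != nrow(cohort)) {
    abort("day must be a scalar or one value per record")
  }
  if (any(day < 0 | day > cohort$followup_end)) {
    abort("day must lie within [0, followup_end] for every record")
  }
  age <- cohort$age_at_index + floor(day / 365.25)
  out <- tibble::tibble(
    female = cohort$sex == "female",
    age_65_74 = age >= 65 & age < 75,
    age_ge75 = age >= 75
  )
  for (comp in names(.components)) {
    onset <- cohort[[.components[[comp]]]]
    out[[comp]] <- !is.na(onset) & onset <= day
  }
  out
}

#' Score a component snapshot
#'
#' @param snap a snapshot tibble from [snapshot()].
#' @param weights a [score_weights()] object.
#' @return integer vector of scores, one per row.
#' @export
score_snapshot <- function(snap, weights) {
  w <- weights$weights
  m <- as.matrix(snap[, .score_components])
  as.integer(m %*% w[.score_components])
}

#' Baseline, follow-up and delta scores per patient
#'
#' The baseline score uses the day-0 snapshot; the follow-up score uses the
#' snapshot at the end of follow-up (fibrillation date for `afl_daf`
#' patients, 3-year assigned window otherwise); delta is their difference,
#' driven by incident comorbidities and ageing across band boundaries.
#'
#' @param cohort a cohort tibble.
#' @param weights a single [score_weights()] object or a list of them.
#' @return a tibble with `patient_id`, `score_name`, `baseline`,
#'   `follow_up`, `delta` (one row per patient and weight set).
#' @export
score_trajectory <- function(cohort, weights) {
  if (inherits(weights, "score_weights")) weights <- list(weights)
  purrr::map_dfr(weights, function(w) {
    base <- score_snapshot(snapshot(cohort, 0L), w)
    fu <- score_snapshot(snapshot(cohort, cohort$followup_end), w)
    tibble::tibble(
      patient_id = cohort$patient_id,
      score_name = w$name,
      baseline = base,
      follow_up = fu,
      delta = fu - base
    )
  })
}
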