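#' Longitudinal atrial-flutter cohort tables
#'
#' A cohort is a tibble with one row per patient. Days are integers relative
#' to the index (atrial-flutter diagnosis) date; day 0 is the index date, a
#' comorbidity with `onset <= 0` is present at baseline, and onsets are
#' permanent. Follow-up is capped at 1095 days (3 years).
#'
#' Columns:
#' \describe{
#'   \item{patient_id}{character, unique.}
#'   \item{sex}{`"female"` or `"male"`.}
#'   \item{age_at_index}{integer years at the index date.}
#'   \item{group}{`"solitary_afl"` (flutter only) or `"afl_daf"` (flutter
#'     that developed fibrillation during follow-up).}
#'   \item{hf_onset, htn_onset, dm_onset, stroke_onset, vasc_onset,
#'     copd_onset}{integer onset day of heart failure, hypertension,
#'     diabetes, stroke/TIA, vascular disease, COPD; `NA` = never.}
#'   \item{followup_end}{integer day in 1..1095.}
#'   \item{af_day}{day atrial fibrillation was diagnosed (`afl_daf` only;
#'     equals `followup_end`).}
#'   \item{stroke_day}{day of first ischaemic-stroke hospitalisation after
#'     index, or `NA`.}
#'   \item{prior_af, ablation, died}{logical flags: fibrillation before/at
#'     index, catheter ablation of flutter during follow-up, death during
#'     follow-up.}
#' }
#'
#' @name cohort
NULL

.cohort_cols <- c(
  "patient_id", "sex", "age_at_index", "group",
  "hf_onset", "htn_onset", "dm_onset", "stroke_onset", "vasc_onset",
  "copd_onset", "followup_end", "af_day", "stroke_day",
  "prior_af", "ablation", "died"
)

make_empty_cohort <- function() {
  tibble::tibble(
    patient_id = character(), sex = character(), age_at_index = integer(),
    group = character(), hf_onset = integer(), htn_onset = integer(),
    dm_onset = integer(), stroke_onset = integer(), vasc_onset = integer(),
    copd_onset = integer(), followup_end = integer(), af_day = integer(),
    stroke_day = integer(), prior_af = logical(), ablation = logical(),
    died = logical()
  )
}

.mandatory_cols <- c(
  "patient_id", "sex", "age_at_index", "group",
  "followup_end", "prior_af", "ablation", "died"
)

#' Read or write a cohort CSV
#'
#' One row per patient, mandatory header, empty cell = absent, logical flags
#' coded 0/1. `read_cohort(write_cohort(x, path))` is the identity.
#'
#' @param path file path.
#' @return `read_cohort()` returns a cohort tibble (see [cohort]).
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  if (!identical(names(raw), .cohort_cols)) {
    abort(paste0(
      "malformed cohort file: header must be exactly: ",
      paste(.cohort_cols, collapse = ",")
    ))
  }
  int_cols <- setdiff(.cohort_cols, c("patient_id", "sex", "group",
                                      "prior_af", "ablation", "died"))
  parse_int <- function(x, col) {
    out <- suppressWarnings(as.integer(x))
    bad <- which(!is.na(x) & x != "" & (is.na(out) | x != as.character(out)))
    if (length(bad)) {
      abort(sprintf("parse error in column '%s', row %d: '%s' is not an integer",
                    col, bad[1], x[bad[1]]))
    }
    out[x == ""] <- NA_integer_
    out
  }
  parse_bool <- function(x, col) {
    bad <- which(!x %in% c("0", "1", ""))
    if (length(bad)) {
      abort(sprintf("parse error in column '%s', row %d: '%s' is not 0/1",
                    col, bad[1], x[bad[1]]))
    }
    ifelse(x == "", NA, x == "1")
  }
  out <- raw
  for (col in int_cols) out[[col]] <- parse_int(raw[[col]], col)
  for (col in c("prior_af", "ablation", "died")) {
    out[[col]] <- parse_bool(raw[[col]], col)
  }
  out$patient_id[out$patient_id == ""] <- NA_character_
  out$sex[!out$sex %in% c("female", "male")] <- NA_character_
  out$group[!out$group %in% .groups] <- NA_character_
  tibble::as_tibble(out)
}

#' @rdname read_cohort
#' @param cohort a cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort[, .cohort_cols]
  for (col in c("prior_af", "ablation", "died")) {
    out[[col]] <- as.integer(out[[col]])
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Apply the eligibility filters
#'
#' Excludes, in order: (1) records with a missing mandatory field or age
#' under 20 years, (2) records with atrial fibrillation before or at the
#' index date (`prior_af`, or `af_day <= 0`), (3) records ablated during
#' follow-up. Each record is tallied once, under the first rule it violates.
#'
#' @param cohort a cohort tibble.
#' @return a list with `cohort` (the eligible records) and `report`, a
#'   one-row tibble of exclusion counts.
#' @export
apply_eligibility <- function(cohort) {
  n_input <- nrow(cohort)
  if (n_input == 0) {
    return(list(
      cohort = cohort,
      report = tibble::tibble(
        n_input = 0L, n_excluded_missing_or_young = 0L,
        n_excluded_prior_af = 0L, n_excluded_ablation = 0L, n_eligible = 0L
      )
    ))
  }
  missing_mand <- Reduce(`|`, lapply(.mandatory_cols, function(col) {
    is.na(cohort[[col]])
  }))
  # afl_daf records must carry the fibrillation date
  missing_mand <- missing_mand |
    (!is.na(cohort$group) & cohort$group == "afl_daf" & is.na(cohort$af_day))
  rule1 <- missing_mand | (!is.na(cohort$age_at_index) & cohort$age_at_index < 20)
  rule2 <- !rule1 & (cohort$prior_af | (!is.na(cohort$af_day) & cohort$af_day <= 0))
  rule3 <- !rule1 & !rule2 & cohort$ablation
  keep <- !(rule1 | rule2 | rule3)
  list(
    cohort = cohort[keep, , drop = FALSE],
    report = tibble::tibble(
      n_input = n_input,
      n_excluded_missing_or_young = sum(rule1),
      n_excluded_prior_af = sum(rule2),
      n_excluded_ablation = sum(rule3),
      n_eligible = sum(keep)
    )
  )
}

#' Assign counterpart follow-up windows
#'
#' A solitary-flutter patient has no event that ends follow-up, so each is
#' paired with an `afl_daf` patient and inherits that counterpart's
#' fibrillation date as follow-up end. This makes the follow-up duration
#' distributions identical between groups by construction.
#'
#' @param cohort a cohort tibble containing both members of every pair.
#' @param pairs a tibble with columns `solitary_id` and `afl_daf_id`.
#' @return the cohort with solitary `followup_end` updated.
#' @export
assign_counterpart_followup <- function(cohort, pairs) {
  idx_t <- match(pairs$afl_daf_id, cohort$patient_id)
  idx_c <- match(pairs$solitary_id, cohort$patient_id)
  if (anyNA(idx_t) || anyNA(idx_c)) {
    abort("pairs reference patient ids absent from the cohort")
  }
  if (any(cohort$group[idx_t] != "afl_daf") ||
      any(cohort$group[idx_c] != "solitary_afl")) {
    abort("pairs must list one solitary_afl and one afl_daf member each")
  }
  af <- cohort$af_day[idx_t]
  if (anyNA(af)) {
    abort("invalid pair: an afl_daf counterpart lacks af_day")
  }
  cohort$followup_end[idx_c] <- af
  cohort
}
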