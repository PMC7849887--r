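# Builders for small hand-constructed cohorts.

make_record <- function(patient_id = "P1", sex = "male", age_at_index = 50L,
                        group = "solitary_afl", hf_onset = NA, htn_onset = NA,
                        dm_onset = NA, stroke_onset = NA, vasc_onset = NA,
                        copd_onset = NA, followup_end = 365L, af_day = NA,
                        stroke_day = NA, prior_af = FALSE, ablation = FALSE,
                        died = FALSE) {
  tibble::tibble(
    patient_id = patient_id, sex = sex,
    age_at_index = as.integer(age_at_index), group = group,
    hf_onset = as.integer(hf_onset), htn_onset = as.integer(htn_onset),
    dm_onset = as.integer(dm_onset), stroke_onset = as.integer(stroke_onset),
    vasc_onset = as.integer(vasc_onset), copd_onset = as.integer(copd_onset),
    followup_end = as.integer(followup_end), af_day = as.integer(af_day),
    stroke_day = as.integer(stroke_day), prior_af = prior_af,
    ablation = ablation, died = died
  )
}

make_cohort <- function(...) dplyr::bind_rows(...)

# small, fast generator settings for structural tests
small_params <- function(n = 300, ...) cohort_params(n_per_group = n, ...)

# pre-matching style parameters with deliberate baseline imbalance
imbalanced_params <- function(n = 3000) {
  cohort_params(
    n_per_group = n,
    baseline_prevalence = list(
      solitary_afl = c(heart_failure = 0.133, hypertension = 0.572,
                       diabetes = 0.188, stroke_tia = 0.150,
                       vascular_disease = 0.371, copd = 0.182),
      afl_daf = c(heart_failure = 0.170, hypertension = 0.599,
                  diabetes = 0.185, stroke_tia = 0.157,
                  vascular_disease = 0.421, copd = 0.207)
    ),
    female_prob = list(solitary_afl = 0.398, afl_daf = 0.382),
    age_band_probs = list(solitary_afl = c(0.346, 0.260, 0.394),
                          afl_daf = c(0.270, 0.284, 0.446))
  )
}

# brute-force all-pairs concordance oracle for the AUC
auc_brute_force <- function(scores, outcome) {
  x <- scores[as.logical(outcome)]
  y <- scores[!as.logical(outcome)]
  total <- 0
  for (xi in x) total <- total + sum(xi > y) + 0.5 * sum(xi == y)
  total / (length(x) * length(y))
}
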