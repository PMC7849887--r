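#' Pipeline configuration
#'
#' A pipeline config is a plain list: `generator` (arguments to
#' [cohort_params()]), `matching` (`caliper_multiplier`, `order_seed`),
#' `scores` (two scoring-system names, reference first), `min_stratum`
#' (risk-table top-coding), and `seed` (global seed; per-stage seeds are
#' derived from it so stages re-run identically in isolation).
#'
#' @param path YAML file to read, or `NULL` for the shipped defaults.
#' @return `validate_config()` returns the validated config list, or raises
#'   one error listing every violation.
#' @export
validate_config <- function(path = NULL) {
  cfg <- if (is.null(path)) {
    yaml::read_yaml(system.file("config", "default_config.yaml",
                                package = "flutterscore"))
  } else if (is.character(path)) {
    if (!file.exists(path)) abort(sprintf("cannot read config file '%s'", path))
    yaml::read_yaml(path)
  } else {
    path
  }
  errs <- character()
  gen <- cfg$generator %||% list()
  params <- tryCatch(do.call(cohort_params, gen), error = function(e) {
    errs <<- c(errs, sprintf("generator: %s", conditionMessage(e)))
    NULL
  })
  cm <- cfg$matching$caliper_multiplier %||% 0.2
  if (!is.numeric(cm) || cm <= 0) {
    errs <- c(errs, "matching$caliper_multiplier: must be a positive number")
  }
  valid_scores <- c("chads_vasc", "a2c2s2_vasc", "hatch")
  scores <- cfg$scores %||% c("chads_vasc", "a2c2s2_vasc")
  if (!all(scores %in% valid_scores)) {
    errs <- c(errs, sprintf(
      "scores: unknown name(s) %s; valid names: %s",
      paste(setdiff(scores, valid_scores), collapse = ", "),
      paste(valid_scores, collapse = ", ")))
  }
  if (length(scores) != 2) {
    errs <- c(errs, "scores: exactly two scoring systems are compared")
  }
  ms <- cfg$min_stratum %||% 20
  if (!is.numeric(ms) || ms < 1) {
    errs <- c(errs, "min_stratum: must be a positive number")
  }
  seed <- cfg$seed %||% 1L
  if (!is.numeric(seed) || seed != round(seed)) {
    errs <- c(errs, "seed: must be an integer")
  }
  if (length(errs)) abort(paste(errs, collapse = "\n"))
  list(
    generator = params,
    matching = list(caliper_multiplier = cm,
                    order_seed = cfg$matching$order_seed %||% NA),
    scores = scores,
    min_stratum = ms,
    seed = as.integer(seed)
  )
}

# deterministic per-stage seeds from the global seed (kept below 2^31)
.stage_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: generate a synthetic cohort, apply eligibility
#' filters, fit the propensity model and greedy-match with caliper, score
#' the matched cohort under both systems, tabulate balance, derive the
#' reweighted system from the delta balance rows, compute relative-risk
#' tables for fibrillation development by follow-up and delta score, and
#' compare discrimination of delta vs follow-up (and system vs system) for
#' post-index ischaemic stroke. All artifacts plus a manifest of seeds and
#' per-stage counts are written under `out_dir`; identical config and seed
#' give identical outputs.
#'
#' @param config a config from [validate_config()] (default: shipped
#'   defaults).
#' @param out_dir output directory (created if missing).
#' @param seed optional override of the config's global seed.
#' @param quiet suppress per-stage messages.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config = validate_config(), out_dir, seed = NULL,
                         quiet = FALSE) {
  seed <- as.integer(seed %||% config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(seed = seed, stages = list(),
                   package_version = as.character(
                     utils::packageVersion("flutterscore")))

  say("[simulate] generating synthetic cohort (n = %d per group)",
      config$generator$n_per_group)
  cohort <- generate_cohort(config$generator, seed = .stage_seed(seed, 1))
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  manifest$stages$simulate <- list(seed = .stage_seed(seed, 1),
                                   n_records = nrow(cohort))

  elig <- apply_eligibility(cohort)
  cohort <- elig$cohort
  say("[eligibility] %d of %d records eligible",
      elig$report$n_eligible, elig$report$n_input)
  manifest$stages$eligibility <- as.list(elig$report)

  order_seed <- config$matching$order_seed
  if (is.na(order_seed)) order_seed <- .stage_seed(seed, 2)
  fit <- fit_propensity(cohort)
  match <- greedy_match(fit, config$matching$caliper_multiplier,
                        order_seed = order_seed)
  readr::write_csv(match$pairs, file.path(out_dir, "matches.csv"),
                   progress = FALSE)
  matched <- match_summary(match, cohort)$cohort
  say("[match] %d pairs (caliper %.4f), %d treated unmatched",
      nrow(match$pairs), match$caliper_value, match$n_unmatched_treated)
  manifest$stages$match <- list(
    order_seed = order_seed, n_pairs = nrow(match$pairs),
    caliper_value = match$caliper_value,
    n_unmatched_treated = match$n_unmatched_treated)

  weights <- lapply(config$scores, score_weights)
  traj <- score_trajectory(matched, weights)
  readr::write_csv(traj, file.path(out_dir, "scores.csv"), progress = FALSE)
  manifest$stages$score <- list(n_rows = nrow(traj),
                                systems = config$scores)

  bal <- balance_table(matched, weights = weights)
  bal_out <- dplyr::mutate(tibble::as_tibble(bal),
                           std = round(.data$std, 2))
  readr::write_csv(bal_out, file.path(out_dir, "balance.csv"),
                   progress = FALSE)
  jsonlite::write_json(bal_out, file.path(out_dir, "balance.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages$balance <- list(n_rows = nrow(bal))

  derived <- derive_weights(bal, base = score_weights(config$scores[[1]]),
                            name = "derived")
  yaml::write_yaml(list(name = derived$name,
                        weights = as.list(derived$weights)),
                   file.path(out_dir, "derived_weights.yaml"))
  say("[derive-weights] %s", paste(sprintf("%s=%d", names(derived$weights),
                                           derived$weights), collapse = " "))
  manifest$stages$derive_weights <- as.list(derived$weights)

  af <- matched$group == "afl_daf"
  risk <- purrr::map_dfr(weights, function(w) {
    tw <- traj[traj$score_name == w$name, ]
    tw <- tw[match(matched$patient_id, tw$patient_id), ]
    purrr::map_dfr(c("follow_up", "delta"), function(tp) {
      rt <- risk_table(
        tibble::tibble(score = tw[[tp]], af = af), "score", "af",
        min_stratum = config$min_stratum)
      dplyr::mutate(tibble::as_tibble(rt), score_name = w$name,
                    timepoint = tp, .before = 1)
    })
  })
  readr::write_csv(risk, file.path(out_dir, "risk.csv"), progress = FALSE)
  manifest$stages$risk <- list(n_rows = nrow(risk))

  disc <- discrimination_report(matched, weights = weights)
  jsonlite::write_json(disc, file.path(out_dir, "discrimination.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages$discrimination <- list(n_rows = nrow(disc))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] artifacts written to %s", out_dir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
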