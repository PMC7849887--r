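#' Default propensity covariates for a cohort
#'
#' Baseline (day-0) design: the CHA2DS2-VASc score, its components (female
#' sex, age bands, heart failure, hypertension, diabetes, stroke/TIA,
#' vascular disease), COPD, and the HATCH score. Additional columns can be
#' bound by the caller before fitting.
#'
#' @param cohort a cohort tibble.
#' @return a tibble of numeric covariates, rows aligned with `cohort`.
#' @export
propensity_covariates <- function(cohort) {
  snap <- snapshot(cohort, 0L)
  out <- tibble::as_tibble(lapply(snap, as.numeric))
  out$chads_vasc_score <- as.numeric(
    score_snapshot(snap, score_weights("chads_vasc")))
  out$hatch_score <- as.numeric(
    score_snapshot(snap, score_weights("hatch")))
  out
}

#' Fit the propensity model
#'
#' Maximum-likelihood logistic regression of group membership (`afl_daf` vs
#' `solitary_afl`) on main effects only (no interactions), by iteratively
#' reweighted least squares (relative tolerance 1e-8, at most 100
#' iterations). Constant or collinear covariates are dropped with a
#' warning; perfect separation is an error naming the separating covariate.
#'
#' @param cohort a cohort tibble.
#' @param covariates optional data frame of numeric covariates aligned with
#'   `cohort` (default [propensity_covariates()]).
#' @return a `propensity_fit` with per-patient propensity scores and logits.
#' @export
fit_propensity <- function(cohort, covariates = NULL) {
  if (length(unique(cohort$group)) < 2 ||
      min(table(cohort$group)) < 2) {
    abort("fit_propensity needs at least 2 patients in each group")
  }
  if (is.null(covariates)) covariates <- propensity_covariates(cohort)
  covariates <- tibble::as_tibble(covariates)
  stopifnot(nrow(covariates) == nrow(cohort))
  treated <- as.integer(cohort$group == "afl_daf")

  # drop constants, then resolve exact collinearity by QR rank
  dropped <- character()
  is_const <- vapply(covariates, function(x) var(x) == 0, logical(1))
  if (any(is_const)) {
    dropped <- names(covariates)[is_const]
    warn(sprintf("dropping constant covariate(s): %s",
                 paste(dropped, collapse = ", ")))
    covariates <- covariates[, !is_const, drop = FALSE]
  }
  x <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    coll <- colnames(x)[-keep]
    warn(sprintf("dropping collinear covariate(s): %s",
                 paste(coll, collapse = ", ")))
    dropped <- c(dropped, coll)
    covariates <- covariates[, setdiff(colnames(covariates), coll),
                             drop = FALSE]
  }

  # a binary covariate splitting the groups exactly separates the fit
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (all(v %in% c(0, 1))) {
      t1 <- tapply(treated, v, mean)
      if (length(t1) == 2 && all(t1 %in% c(0, 1)) && t1[1] != t1[2]) {
        abort(sprintf("perfect separation on covariate '%s'", nm))
      }
    }
  }

  dat <- cbind(tibble::tibble(..treated = treated), covariates)
  fit <- glm(..treated ~ ., data = dat, family = binomial(),
             control = glm.control(epsilon = 1e-8, maxit = 100))
  ps <- as.numeric(fit$fitted.values)
  if (any(ps < 1e-10 | ps > 1 - 1e-10)) {
    abort("perfect separation: fitted propensities reached 0/1")
  }
  structure(list(
    model = fit,
    coefficients = coef(fit),
    dropped = dropped,
    converged = fit$converged,
    n_iterations = fit$iter,
    scores = tibble::tibble(
      patient_id = cohort$patient_id,
      group = cohort$group,
      propensity = ps,
      logit = qlogis(ps)
    )
  ), class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat(sprintf("<propensity_fit> %d patients, %d covariates%s, %s\n",
              nrow(x$scores), length(x$coefficients) - 1,
              if (length(x$dropped))
                sprintf(" (%d dropped)", length(x$dropped)) else "",
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
tidy.propensity_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(s), estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @export
glance.propensity_fit <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$scores),
    n_covariates = length(x$coefficients) - 1L,
    converged = x$converged,
    n_iterations = x$n_iterations,
    deviance = x$model$deviance,
    aic = x$model$aic
  )
}

#' Greedy nearest-neighbour matching with a caliper
#'
#' Treated (`afl_daf`) patients are visited in a seeded random order; each
#' takes the unused control (`solitary_afl`) with the smallest absolute
#' propensity-logit difference, or stays unmatched when that minimum
#' exceeds the caliper. Matching is 1:1 without replacement; the caliper is
#' `caliper_multiplier` times the SD of the logit propensity over the
#' pooled sample. Distance ties break to the lowest control id.
#'
#' @param fit a [fit_propensity()] object.
#' @param caliper_multiplier positive scale for the caliper (default 0.2).
#' @param order_seed seed for the treated traversal order.
#' @return a `match_result`: `pairs` tibble (`afl_daf_id`, `solitary_id`,
#'   `logit_distance`), `caliper_value`, `n_unmatched_treated`,
#'   `order_seed`.
#' @export
greedy_match <- function(fit, caliper_multiplier = 0.2, order_seed = 1L) {
  stopifnot(inherits(fit, "propensity_fit"))
  if (!is.numeric(caliper_multiplier) || caliper_multiplier <= 0) {
    abort("caliper_multiplier must be a positive number")
  }
  sc <- fit$scores
  caliper <- caliper_multiplier * sd(sc$logit)
  tr <- sc[sc$group == "afl_daf", ]
  co <- sc[sc$group == "solitary_afl", ]
  co <- co[order(co$patient_id), ]
  perm <- withr::with_seed(order_seed, sample.int(nrow(tr)))
  tr <- tr[perm, ]

  n_t <- nrow(tr)
  avail <- rep(TRUE, nrow(co))
  m_treated <- character(n_t)
  m_control <- character(n_t)
  m_dist <- numeric(n_t)
  k <- 0L
  cl <- co$logit
  for (i in seq_len(n_t)) {
    if (!any(avail)) break
    d <- abs(cl - tr$logit[i])
    d[!avail] <- Inf
    j <- which.min(d)
    if (d[j] <= caliper) {
      k <- k + 1L
      m_treated[k] <- tr$patient_id[i]
      m_control[k] <- co$patient_id[j]
      m_dist[k] <- d[j]
      avail[j] <- FALSE
    }
  }
  pairs <- tibble::tibble(
    afl_daf_id = m_treated[seq_len(k)],
    solitary_id = m_control[seq_len(k)],
    logit_distance = m_dist[seq_len(k)]
  )
  structure(list(
    pairs = pairs,
    caliper_value = caliper,
    n_unmatched_treated = n_t - k,
    order_seed = order_seed
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %d pairs, %d treated unmatched, caliper %.4f (logit)\n",
    nrow(x$pairs), x$n_unmatched_treated, x$caliper_value))
  invisible(x)
}

#' @export
tidy.match_result <- function(x, ...) x$pairs

#' @export
glance.match_result <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    n_unmatched_treated = x$n_unmatched_treated,
    caliper_value = x$caliper_value,
    mean_logit_distance = mean(x$pairs$logit_distance),
    order_seed = x$order_seed
  )
}

#' Extract the matched sub-cohort
#'
#' @param result a [greedy_match()] result.
#' @param cohort the cohort the match was computed on.
#' @return a list with `cohort` (both members of every pair) and `counts`,
#'   a per-group tibble.
#' @export
match_summary <- function(result, cohort) {
  ids <- c(result$pairs$afl_daf_id, result$pairs$solitary_id)
  if (!all(ids %in% cohort$patient_id)) {
    abort("match result references patient ids absent from the cohort")
  }
  matched <- cohort[cohort$patient_id %in% ids, , drop = FALSE]
  counts <- dplyr::count(matched, .data$group, name = "n")
  list(cohort = matched, counts = counts)
}
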