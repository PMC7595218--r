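# Visual-outcome association: LOCF imputation of follow-up visual acuity and
# linear regression of logMAR change on the CNV score (optionally adjusted
# for age, sex and baseline logMAR).

#' Last-observation-carried-forward imputation of follow-up visits
#'
#' For each patient and each target month whose logMAR is missing (or whose
#' visit is absent), the most recent earlier non-missing observation —
#' scheduled or not — is carried forward.  Baseline (month 0) must be
#' present and non-missing.  Patients with no post-baseline observation
#' cannot be imputed and are flagged for exclusion.
#'
#' @param visits Visit tibble (`patient_id`, `month`, `logmar`), months
#'   increasing within patient.
#' @param target_months Months to complete (default `c(3, 12)`).
#' @return A tibble `patient_id`, `month`, `logmar`, `imputed` (logical)
#'   restricted to baseline + target months, with attributes `n_imputed`
#'   (per target month) and `no_followup` (patient ids flagged for
#'   exclusion).
#' @export
locf_impute <- function(visits, target_months = c(3L, 12L)) {
  stopifnot(all(c("patient_id", "month", "logmar") %in% names(visits)))
  ids <- unique(visits$patient_id)
  rows <- vector("list", length(ids))
  no_followup <- character(0)
  n_imputed <- stats::setNames(integer(length(target_months)),
                               as.character(target_months))
  for (i in seq_along(ids)) {
    v <- visits[visits$patient_id == ids[i], , drop = FALSE]
    v <- v[order(v$month), , drop = FALSE]
    base <- v$logmar[v$month == 0L]
    if (length(base) != 1L || is.na(base)) {
      stop("patient ", ids[i], " lacks a non-missing baseline visit", call. = FALSE)
    }
    observed <- v[!is.na(v$logmar), , drop = FALSE]
    if (all(observed$month == 0L)) no_followup <- c(no_followup, ids[i])
    out <- tibble::tibble(
      patient_id = ids[i],
      month = as.integer(c(0L, target_months)),
      logmar = NA_real_, imputed = FALSE
    )
    out$logmar[1L] <- base
    for (j in seq_along(target_months)) {
      m <- target_months[j]
      direct <- v$logmar[v$month == m]
      if (length(direct) == 1L && !is.na(direct)) {
        out$logmar[j + 1L] <- direct
      } else {
        earlier <- observed[observed$month < m, , drop = FALSE]
        out$logmar[j + 1L] <- earlier$logmar[nrow(earlier)]
        out$imputed[j + 1L] <- TRUE
        n_imputed[as.character(m)] <- n_imputed[as.character(m)] + 1L
      }
    }
    rows[[i]] <- out
  }
  res <- do.call(rbind, rows)
  attr(res, "n_imputed") <- n_imputed
  attr(res, "no_followup") <- no_followup
  res
}

#' Change in logMAR from baseline
#'
#' `logMAR(month) - logMAR(0)`; negative change is visual improvement.
#'
#' @param visits Visit tibble for one or more patients (possibly LOCF
#'   completed).
#' @param month Target month.
#' @return A tibble `patient_id`, `change` (`NA` where the month is
#'   unavailable).
#' @export
bcva_change <- function(visits, month) {
  ids <- unique(visits$patient_id)
  change <- vapply(ids, function(id) {
    v <- visits[visits$patient_id == id, , drop = FALSE]
    base <- v$logmar[v$month == 0L]
    at <- v$logmar[v$month == month]
    if (length(base) != 1L || length(at) != 1L) return(NA_real_)
    at - base
  }, numeric(1))
  tibble::tibble(patient_id = ids, change = unname(change))
}

#' Linear regression of visual-acuity change on the CNV score
#'
#' Ordinary least squares of logMAR change on the score (unadjusted) or on
#' score + age + sex + baseline logMAR (adjusted).  Standard errors come
#' from the residual variance times the inverse Gram diagonal; p-values are
#' two-sided t tests on n - p - 1 degrees of freedom.
#'
#' @param data Tibble with columns `change`, `score`, and (for the adjusted
#'   model) `age`, `sex`, `baseline_logmar`; complete cases only.
#' @param adjust Adjust for age, sex and baseline logMAR (default `TRUE`).
#' @return A `regression_result`: `coefficients` (B), `se`, `p_value`, `n`,
#'   `adjusted`, `fit` (the underlying `lm`).
#' @export
fit_outcome_regression <- function(data, adjust = TRUE) {
  needed <- if (adjust) c("change", "score", "age", "sex", "baseline_logmar")
            else c("change", "score")
  stopifnot(all(needed %in% names(data)))
  data <- data[stats::complete.cases(data[, needed]), needed, drop = FALSE]
  if (nrow(data) <= length(needed)) {
    stop("too few complete cases for regression", call. = FALSE)
  }
  form <- if (adjust) change ~ score + age + sex + baseline_logmar
          else change ~ score
  fit <- stats::lm(form, data = data)
  if (fit$rank < length(stats::coef(fit)) || anyNA(stats::coef(fit))) {
    stop("rank-deficient design: collinear regressors", call. = FALSE)
  }
  sm <- summary(fit)
  structure(
    list(coefficients = stats::coef(fit),
         se = sm$coefficients[, "Std. Error"],
         p_value = sm$coefficients[, "Pr(>|t|)"],
         n = nrow(data), adjusted = adjust, fit = fit),
    class = "regression_result"
  )
}

#' Score-outcome association table (both months, both adjustments)
#'
#' LOCF-completes the visit table, excludes patients without any
#' post-baseline observation, computes logMAR change at each target month,
#' and fits the unadjusted and adjusted regressions of change on the score.
#'
#' @param cohort Cohort tibble (for age, sex, baseline logMAR).
#' @param visits Visit tibble.
#' @param scores Named or positional score vector aligned with `cohort`.
#' @param months Target months (default `c(3, 12)`).
#' @param eligible Optional logical vector aligned with `cohort`: treatment
#'   eligibility (e.g. a fixed anti-VEGF regimen inclusion flag); `NULL`
#'   keeps everyone.
#' @return A tibble: `month`, `adjusted`, `b_score`, `se_score`, `p_score`,
#'   `n`.
#' @export
outcome_association <- function(cohort, visits, scores, months = c(3L, 12L),
                                eligible = NULL) {
  if (!is.null(eligible)) {
    stopifnot(length(eligible) == nrow(cohort))
    keep <- which(eligible)
    scores <- scores[keep]
    cohort <- cohort[keep, , drop = FALSE]
    visits <- visits[visits$patient_id %in% cohort$patient_id, , drop = FALSE]
  }
  imp <- locf_impute(visits, target_months = months)
  excluded <- attr(imp, "no_followup")
  base <- tibble::tibble(
    patient_id = cohort$patient_id, score = scores,
    age = cohort$age, sex = cohort$sex,
    baseline_logmar = cohort$logmar_affected
  )
  rows <- list()
  for (m in months) {
    ch <- bcva_change(imp, m)
    dat <- merge(base, ch, by = "patient_id")
    dat <- dat[!(dat$patient_id %in% excluded), , drop = FALSE]
    for (adj in c(FALSE, TRUE)) {
      fit <- fit_outcome_regression(dat, adjust = adj)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        month = m, adjusted = adj,
        b_score = unname(fit$coefficients["score"]),
        se_score = unname(fit$se["score"]),
        p_score = unname(fit$p_value["score"]),
        n = fit$n
      )
    }
  }
  do.call(rbind, rows)
}
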