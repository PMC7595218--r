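# The CNV score: a 7-parameter logistic log-odds score separating PNV-type
# (pachychoroid) from AMD-type disease, plus its derivation (train/validation
# split, logistic fit), threshold diagnostics and cutoff-bin PPVs.

#' Score weights (intercept + seven unit-scaled terms)
#'
#' `published_weights()` returns the published scoring system: log-odds
#' weights on age (per 10 years), sex (female = 1), CVH in either eye,
#' affected-eye central retinal thickness (per 100 um), affected- and
#' fellow-eye subfoveal choroidal thickness (per 100 um), and type A (soft)
#' drusen in either eye, with intercept -7.04.  A positive score means
#' PNV-type is more likely than AMD-type.
#'
#' @param intercept Intercept on the log-odds scale.
#' @param terms Tibble with columns `term` (feature name), `divisor` (unit
#'   scaling: the raw value is divided by it before weighting) and `weight`.
#' @return A `score_weights` object.
#' @export
#' @examples
#' published_weights()
score_weights <- function(intercept, terms) {
  stopifnot(is.numeric(intercept), nrow(terms) == 7L,
            all(c("term", "divisor", "weight") %in% names(terms)),
            all(terms$divisor > 0))
  structure(list(intercept = intercept, terms = terms),
            class = "score_weights")
}

#' @rdname score_weights
#' @export
published_weights <- function() {
  score_weights(
    intercept = -7.04,
    terms = tibble::tribble(
      ~term,                        ~divisor, ~weight,
      "age",                             10,    0.16,
      "sex",                              1,    0.52,
      "cvh_either",                       1,    1.99,
      "retinal_thickness_affected",     100,   -0.34,
      "sfct_affected",                  100,    1.37,
      "sfct_fellow",                    100,    1.24,
      "drusen_a_either",                  1,   -1.68
    )
  )
}

#' @export
print.score_weights <- function(x, ...) {
  cat("CNV score weights (intercept", format(x$intercept), ")\n")
  print(as.data.frame(x$terms))
  invisible(x)
}

#' Compute the CNV score
#'
#' score = intercept + sum_i weight_i * (value_i / divisor_i).  Higher
#' scores indicate PNV-type (probability of PNV-type is
#' `plogis(score)`).
#'
#' @param records Cohort tibble (or one-row record) containing the seven
#'   score covariates.
#' @param weights A [score_weights()] object (default: the published
#'   weights).
#' @return Numeric vector of scores, one per record.
#' @export
#' @examples
#' pt <- tibble::tibble(age = 66, sex = 0, cvh_either = 1,
#'                      retinal_thickness_affected = 455,
#'                      sfct_affected = 508, sfct_fellow = 503,
#'                      drusen_a_either = 0)
#' cnv_score(pt)  # 7.656
cnv_score <- function(records, weights = published_weights()) {
  terms <- weights$terms
  absent <- setdiff(terms$term, names(records))
  if (length(absent) > 0L) {
    stop("score covariates missing from records: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  score <- rep(weights$intercept, nrow(records))
  for (i in seq_len(nrow(terms))) {
    v <- records[[terms$term[i]]]
    if (anyNA(v)) {
      stop("missing value in score covariate: ", terms$term[i], call. = FALSE)
    }
    score <- score + terms$weight[i] * (v / terms$divisor[i])
  }
  score
}

#' Random train/validation split
#'
#' Partitions the cohort at the given ratio; the validation set takes
#' `ceiling(n * valid / (train + valid))` records, so 537 records at 3:1
#' give 402 training and 135 validation.  Seed-deterministic.
#'
#' @param cohort Cohort tibble.
#' @param ratio Length-2 integer vector `c(train_parts, valid_parts)`.
#' @param seed Integer seed.
#' @return A list with `training` and `validation` tibbles (disjoint,
#'   exhaustive).
#' @export
split_train_validation <- function(cohort, ratio = c(3, 1), seed = 1L) {
  n <- nrow(cohort)
  if (n == 0L) stop("empty cohort", call. = FALSE)
  stopifnot(length(ratio) == 2L, all(ratio > 0), n >= sum(ratio))
  n_valid <- ceiling(n * ratio[2L] / sum(ratio))
  with_seed(seed, {
    idx <- sample.int(n, n_valid)
    list(training = cohort[-idx, , drop = FALSE],
         validation = cohort[idx, , drop = FALSE])
  })
}

#' Logistic regression of cluster membership on the score predictors
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares)
#' of PNV-type membership on the unit-scaled predictors (age/10,
#' thicknesses/100, binaries as 0/1).  Wald standard errors come from the
#' inverse observed information; odds ratios are `exp(beta)` with 95% CI
#' `exp(beta +/- 1.959964 * SE)`.
#'
#' @param training Cohort tibble containing the predictors.
#' @param labels Character or 0/1 vector: the cluster label per record
#'   (`"PNV-type"` = 1).
#' @param predictors Tibble with columns `term` and `divisor` (defaults to
#'   the seven published score predictors and their unit scalings).
#' @return A `logistic_model`: `coefficients`, `se`, `or`, `ci_low`,
#'   `ci_high`, `p_value` (Wald, two-sided), `predictors`, `converged`,
#'   `n_iter`, `n`.
#' @export
fit_logistic <- function(training, labels,
                         predictors = published_weights()$terms[, c("term", "divisor")]) {
  y <- if (is.numeric(labels)) labels else as.integer(labels == "PNV-type")
  if (length(unique(y)) < 2L) {
    stop("both classes must be present to fit", call. = FALSE)
  }
  dat <- data.frame(.y = y)
  for (i in seq_len(nrow(predictors))) {
    dat[[predictors$term[i]]] <- training[[predictors$term[i]]] / predictors$divisor[i]
  }
  if (anyNA(dat)) stop("predictors must be complete", call. = FALSE)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  if (separation || !fit$converged) {
    big <- names(which(abs(stats::coef(fit)[-1L]) > 10))
    stop("logistic fit did not converge (possible perfect separation",
         if (length(big)) paste0("; suspect predictors: ",
                                 paste(big, collapse = ", ")),
         ")", call. = FALSE)
  }
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc)))) {
    stop("singular information matrix: collinear predictors", call. = FALSE)
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(vc))
  z95 <- 1.959964
  structure(
    list(coefficients = beta, se = se, or = exp(beta),
         ci_low = exp(beta - z95 * se), ci_high = exp(beta + z95 * se),
         p_value = 2 * stats::pnorm(-abs(beta / se)),
         predictors = predictors, converged = TRUE,
         n_iter = fit$iter, n = nrow(dat)),
    class = "logistic_model"
  )
}

#' Turn a fitted logistic model into score weights
#'
#' The scoring system is the model's log-odds coefficients, rounded to
#' `decimals` places (the published table rounds to 2); `decimals = NULL`
#' keeps the coefficients exact.
#'
#' @param model A `logistic_model` from [fit_logistic()].
#' @param decimals Rounding for the published-style score (default 2), or
#'   `NULL` for no rounding.
#' @return A [score_weights()] object with a `rounded` attribute.
#' @export
weights_from_model <- function(model, decimals = 2L) {
  stopifnot(inherits(model, "logistic_model"), isTRUE(model$converged))
  beta <- model$coefficients
  rounder <- if (is.null(decimals)) identity else function(b) round(b, decimals)
  w <- score_weights(
    intercept = rounder(unname(beta["(Intercept)"])),
    terms = tibble::tibble(
      term = model$predictors$term,
      divisor = model$predictors$divisor,
      weight = rounder(unname(beta[model$predictors$term]))
    )
  )
  attr(w, "rounded") <- !is.null(decimals)
  w
}

#' Threshold diagnostics of the score on a labeled validation set
#'
#' Classifies PNV-type where score > `threshold` (default 0, the canonical
#' logistic decision point, probability 0.5), computes the confusion counts,
#' accuracy, sensitivity (PNV correctly called) and specificity (AMD
#' correctly called), sweeps all observed scores as thresholds for the ROC
#' curve, and integrates the AUC by the trapezoid rule.
#'
#' @param scores Numeric score per record.
#' @param labels Cluster label per record (`"PNV-type"` positive), or 0/1.
#' @param threshold Classification threshold on the score scale.
#' @return An `evaluation_report`: `confusion` (2x2), `accuracy`,
#'   `sensitivity`, `specificity`, `roc` (tibble `threshold`, `fpr`, `tpr`),
#'   `auc`, `threshold`.
#' @export
evaluate_score <- function(scores, labels, threshold = 0) {
  y <- if (is.numeric(labels)) labels else as.integer(labels == "PNV-type")
  stopifnot(length(scores) == length(y))
  if (length(unique(y)) < 2L) {
    stop("degenerate evaluation: only one class present", call. = FALSE)
  }
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- tibble::tibble(
    threshold = cuts,
    tpr = vapply(cuts, function(t) mean(scores[y == 1] >= t), numeric(1)),
    fpr = vapply(cuts, function(t) mean(scores[y == 0] >= t), numeric(1))
  )
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1L) + utils::tail(roc$tpr, -1L)) / 2)
  structure(
    list(
      confusion = matrix(c(tn, fn, fp, tp), 2L, 2L,
                         dimnames = list(predicted = c("AMD-type", "PNV-type"),
                                         truth = c("AMD-type", "PNV-type"))),
      accuracy = (tp + tn) / length(y),
      sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      roc = roc, auc = auc, threshold = threshold
    ),
    class = "evaluation_report"
  )
}

#' Score-cutoff contingency bins and per-bin predictive values
#'
#' Bins the score axis at the given cutoffs into half-open intervals
#' (`(-Inf, c1)`, `[c1, c2)`, ..., `[c_last, Inf)`), counts AMD-type and
#' PNV-type records per bin, and reports each bin's positive predictive
#' value for its direction class: bins entirely above `threshold` predict
#' PNV-type, the others predict AMD-type.  PPV is count/total x 100, rounded
#' to one decimal; empty bins get `NA`, never 0.
#'
#' @param scores Numeric scores.
#' @param labels Cluster labels (`"PNV-type"` positive) or 0/1.
#' @param cutoffs Strictly increasing cutoffs (default: the published
#'   validation-set cutoffs -3.610, -1.966, 0.697, 2.629).
#' @param threshold Score separating AMD-direction from PNV-direction bins.
#' @return A `bin_table` tibble: `bin`, `lower`, `upper`, `n_amd`, `n_pnv`,
#'   `direction`, `ppv`.
#' @export
ppv_bins <- function(scores, labels,
                     cutoffs = c(-3.610, -1.966, 0.697, 2.629),
                     threshold = 0) {
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    stop("cutoffs must be strictly increasing", call. = FALSE)
  }
  y <- if (is.numeric(labels)) labels else as.integer(labels == "PNV-type")
  edges <- c(-Inf, cutoffs, Inf)
  nb <- length(edges) - 1L
  idx <- findInterval(scores, edges, left.open = FALSE, rightmost.closed = FALSE)
  n_amd <- tabulate(idx[y == 0], nbins = nb)
  n_pnv <- tabulate(idx[y == 1], nbins = nb)
  lower <- edges[-length(edges)]
  upper <- edges[-1L]
  direction <- ifelse(lower >= threshold, "PNV-type", "AMD-type")
  total <- n_amd + n_pnv
  hit <- ifelse(direction == "PNV-type", n_pnv, n_amd)
  ppv <- ifelse(total == 0L, NA_real_, round(100 * hit / total, 1L))
  structure(
    tibble::tibble(
      bin = seq_len(nb), lower = lower, upper = upper,
      n_amd = n_amd, n_pnv = n_pnv, direction = direction, ppv = ppv
    ),
    class = c("bin_table", class(tibble::tibble()))
  )
}
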