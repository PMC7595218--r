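test_that("the score is the intercept plus unit-scaled weighted covariates", {
  # all covariates zero, male: intercept only
  zero <- tibble::tibble(age = 0, sex = 0, cvh_either = 0,
                         retinal_thickness_affected = 0, sfct_affected = 0,
                         sfct_fellow = 0, drusen_a_either = 0)
  expect_equal(cnv_score(zero), -7.04)

  # affine in SFCT: +100 um on the affected eye adds exactly 1.37
  pt <- tibble::tibble(age = 70, sex = 1, cvh_either = 1,
                       retinal_thickness_affected = 400, sfct_affected = 300,
                       sfct_fellow = 280, drusen_a_either = 0)
  pt2 <- pt; pt2$sfct_affected <- pt$sfct_affected + 100
  expect_equal(cnv_score(pt2) - cnv_score(pt), 1.37)

  # missing covariate is a named error, never a silent zero
  expect_error(cnv_score(pt[, -3]), "cvh_either")
  pt$age <- NA
  expect_error(cnv_score(pt), "age")
})

test_that("probability transform and classification agree at the 0 threshold", {
  s <- c(-2, -0.1, 0, 0.3, 4)
  expect_equal(plogis(s), 1 / (1 + exp(-s)))
  expect_equal(s > 0, plogis(s) > 0.5)
})

test_that("3:1 split takes the ceiling for validation and is deterministic", {
  cohort <- tibble::tibble(patient_id = sprintf("P%03d", 1:537))
  sp <- split_train_validation(cohort, c(3, 1), seed = 5L)
  expect_equal(nrow(sp$training), 402L)
  expect_equal(nrow(sp$validation), 135L)
  expect_length(intersect(sp$training$patient_id,
                          sp$validation$patient_id), 0L)
  expect_setequal(c(sp$training$patient_id, sp$validation$patient_id),
                  cohort$patient_id)

  sp2 <- split_train_validation(cohort, c(3, 1), seed = 5L)
  expect_identical(sp$validation$patient_id, sp2$validation$patient_id)

  small <- split_train_validation(cohort[1:4, ], c(3, 1), seed = 1L)
  expect_equal(nrow(small$training), 3L)
  expect_equal(nrow(small$validation), 1L)

  expect_error(split_train_validation(cohort[0, ], c(3, 1), seed = 1L),
               "empty")
})

test_that("intercept-only logistic fit on balanced labels returns logit one-half", {
  dat <- tibble::tibble(dummy = rep(1, 40))
  fit <- fit_logistic(dat, rep(c(0, 1), 20),
                      predictors = tibble::tibble(term = character(0),
                                                  divisor = numeric(0)))
  expect_equal(unname(fit$coefficients["(Intercept)"]), 0, tolerance = 1e-6)
})

test_that("a saturated one-predictor fit equals the log cross-product odds ratio", {
  # 2x2 table: exposed 30/50 events, unexposed 10/50
  x <- rep(c(1, 0), each = 50)
  y <- c(rep(1, 30), rep(0, 20), rep(1, 10), rep(0, 40))
  fit <- fit_logistic(tibble::tibble(v = x), y,
                      predictors = tibble::tibble(term = "v", divisor = 1))
  or_oracle <- (30 * 40) / (20 * 10)
  expect_equal(unname(fit$coefficients["v"]), log(or_oracle),
               tolerance = 1e-6)
  expect_equal(unname(fit$or["v"]), or_oracle, tolerance = 1e-5)
  # OR/CI internal consistency
  expect_equal(fit$or, exp(fit$coefficients), tolerance = 1e-9)
  expect_true(all(fit$ci_low < fit$or & fit$or < fit$ci_high))
})

test_that("Wald 95% intervals cover the generating coefficients", {
  set.seed(1234)
  beta <- c(-0.5, 0.8, -0.6, 0.4)  # intercept + 3 slopes
  hits <- matrix(NA, 50, 4)
  for (r in 1:50) {
    n <- 5000L
    x <- matrix(rnorm(3 * n), n, 3)
    eta <- beta[1] + x %*% beta[-1]
    y <- rbinom(n, 1, plogis(eta))
    fit <- fit_logistic(
      tibble::tibble(a = x[, 1], b = x[, 2], c = x[, 3]), y,
      predictors = tibble::tibble(term = c("a", "b", "c"), divisor = 1)
    )
    lo <- log(fit$ci_low); hi <- log(fit$ci_high)
    hits[r, ] <- beta >= lo & beta <= hi
  }
  expect_true(all(colMeans(hits) >= 0.9))
})

test_that("perfect separation is reported, not silently fitted", {
  x <- c(-(1:20), 1:20)
  y <- as.integer(x > 0)
  expect_error(
    fit_logistic(tibble::tibble(v = x), y,
                 predictors = tibble::tibble(term = "v", divisor = 1)),
    "separation"
  )
})

test_that("model-derived weights round the coefficients and audit against ORs", {
  set.seed(77)
  cohort <- simulate_cohort(default_config(), seed = 21L)
  fit <- fit_logistic(cohort, cohort$true_cluster)
  w2 <- weights_from_model(fit, decimals = 2L)
  expect_equal(w2$terms$weight,
               unname(round(fit$coefficients[w2$terms$term], 2L)))
  w_exact <- weights_from_model(fit, decimals = NULL)
  expect_equal(w_exact$terms$weight,
               unname(fit$coefficients[w_exact$terms$term]))
  # double-rounding audit on the OR scale: exp(rounded weight) stays close
  # to the rounded odds ratio
  expect_true(all(abs(exp(w2$terms$weight) -
                        round(fit$or[w2$terms$term], 2)) <= 0.15))
})

test_that("derive-then-evaluate on synthetic splits reaches the expected accuracy", {
  cohort <- simulate_cohort(default_config(), seed = 60L)
  sp <- split_train_validation(cohort, c(3, 1), seed = 61L)
  fit <- fit_logistic(sp$training, sp$training$true_cluster)
  w <- weights_from_model(fit, decimals = 2L)
  ev <- evaluate_score(cnv_score(sp$validation, w),
                       sp$validation$true_cluster)
  expect_gt(ev$accuracy, 0.85)
  expect_gt(ev$auc, 0.9)
})

test_that("evaluation handles separation, null scores, and the concordance identity", {
  # perfectly separated scores
  ev <- evaluate_score(c(1:5, 11:15), rep(c(0, 1), each = 5), threshold = 8)
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$specificity, 1.0)

  # labels independent of scores: AUC near 1/2
  set.seed(3)
  s <- rnorm(2000); y <- rbinom(2000, 1, 0.5)
  expect_lt(abs(evaluate_score(s, y)$auc - 0.5), 0.05)

  # AUC equals the Mann-Whitney concordance probability, ties half-weighted
  for (r in 1:5) {
    set.seed(100 + r)
    s <- sample(1:8, 30, replace = TRUE)  # integer grid forces ties
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(evaluate_score(s, y)$auc, auc_concordance(s, y),
                 tolerance = 1e-10)
  }

  # ROC curve is monotone in both coordinates
  expect_true(all(diff(ev$roc$fpr) >= 0))
  expect_true(all(diff(ev$roc$tpr) >= 0))

  expect_error(evaluate_score(1:5, rep(1, 5)), "one class")
})

test_that("PPV bins reproduce the published validation-table predictive values", {
  tb <- table4_scores_labels()
  bins <- ppv_bins(tb$scores, tb$labels)
  expect_equal(bins$n_amd, c(21, 19, 29, 2, 0))
  expect_equal(bins$n_pnv, c(0, 2, 8, 25, 29))
  expect_equal(bins$ppv, c(100, 90.5, 78.4, 92.6, 100))
  expect_equal(bins$direction,
               c("AMD-type", "AMD-type", "AMD-type", "PNV-type", "PNV-type"))
  expect_equal(sum(bins$n_amd) + sum(bins$n_pnv), length(tb$scores))
})

test_that("PPV bins mark empty bins as undefined and tally like brute force", {
  bins <- ppv_bins(rep(-5, 10), rep("AMD-type", 10))
  expect_equal(bins$ppv[1L], 100)
  expect_true(all(is.na(bins$ppv[-1L])))

  set.seed(8)
  s <- runif(50, -6, 6)
  y <- rbinom(50, 1, 0.5)
  cuts <- c(-3.610, -1.966, 0.697, 2.629)
  bins <- ppv_bins(s, y, cuts)
  edges <- c(-Inf, cuts, Inf)
  for (b in 1:5) {
    in_bin <- s >= edges[b] & s < edges[b + 1]
    expect_equal(bins$n_amd[b], sum(in_bin & y == 0))
    expect_equal(bins$n_pnv[b], sum(in_bin & y == 1))
  }
  expect_error(ppv_bins(s, y, c(1, 1, 2)), "strictly increasing")
})
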