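#!/usr/bin/env Rscript
# Stage 3: derive and evaluate the CNV score.
#
# Split the clustered cohort 3:1 into training and validation, fit the
# 7-predictor logistic model of PNV-type membership on the training set,
# round the coefficients to the 2-decimal scoring system, and evaluate on
# the validation set: accuracy / sensitivity / specificity at score 0, AUC,
# and the cutoff-bin positive predictive values.

suppressPackageStartupMessages(library(pachycnv))
out <- "results"
cohort <- read_cohort(file.path(out, "cohort.csv"))
assignments <- readr::read_csv(file.path(out, "assignments.csv"),
                               show_col_types = FALSE)
labels <- assignments$cluster[match(cohort$patient_id,
                                    assignments$patient_id)]

sp <- split_train_validation(cohort, c(3, 1), seed = 101L)
cat("split:", nrow(sp$training), "training /", nrow(sp$validation),
    "validation\n")

train_labels <- labels[match(sp$training$patient_id, cohort$patient_id)]
valid_labels <- labels[match(sp$validation$patient_id, cohort$patient_id)]
model <- fit_logistic(sp$training, train_labels)
weights <- weights_from_model(model, decimals = 2L)

model_tab <- tibble::tibble(
  term = names(model$coefficients),
  coefficient = unname(model$coefficients), se = unname(model$se),
  or = unname(model$or), ci_low = unname(model$ci_low),
  ci_high = unname(model$ci_high), p_value = unname(model$p_value)
)
readr::write_csv(model_tab, file.path(out, "logistic_model.csv"))
jsonlite::write_json(
  list(intercept = weights$intercept, terms = as.data.frame(weights$terms)),
  file.path(out, "score_weights.json"), auto_unbox = TRUE, digits = NA
)
cat("fitted score weights (rounded):\n"); print(weights)

valid_scores <- cnv_score(sp$validation, weights)
ev <- evaluate_score(valid_scores, valid_labels)
cat(sprintf("validation: accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
            ev$accuracy, ev$sensitivity, ev$specificity, ev$auc))
bins <- ppv_bins(valid_scores, valid_labels)
print(as.data.frame(bins))
readr::write_csv(as.data.frame(bins), file.path(out, "ppv_bins.csv"))
readr::write_csv(
  tibble::tibble(patient_id = cohort$patient_id,
                 score = cnv_score(cohort, weights), cluster = labels),
  file.path(out, "scores.csv")
)
jsonlite::write_json(
  list(accuracy = ev$accuracy, sensitivity = ev$sensitivity,
       specificity = ev$specificity, auc = ev$auc),
  file.path(out, "score_evaluation.json"), auto_unbox = TRUE, digits = NA
)
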