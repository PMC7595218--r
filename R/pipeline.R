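# End-to-end orchestration: simulate (or read) a cohort, filter, cluster,
# split, fit and evaluate the score, bin the validation scores, and associate
# the score with visual outcomes.  Every artifact is re-derivable from the
# config and its seeds alone.

#' Pipeline configuration
#'
#' @param out_dir Output directory for stage artifacts (created if needed).
#' @param cohort_csv,visits_csv Input paths, or `NULL` with
#'   `simulate = TRUE` to generate the inputs from `cohort_config`.
#' @param simulate Generate the cohort instead of reading it.
#' @param cohort_config A [cohort_config()] used when simulating.
#' @param seeds Named integer list: `cohort`, `split`, `clustering`.
#' @param k_max,B,rule,n_restarts Clustering parameters, see
#'   [cluster_cohort()].
#' @param ratio Train:validation ratio (default `c(3, 1)`).
#' @param decimals Rounding of fitted weights (default 2).
#' @param cutoffs Score cutoffs for the PPV bins.
#' @param threshold Classification threshold (default 0).
#' @param schema Feature schema.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            cohort_csv = NULL, visits_csv = NULL,
                            simulate = is.null(cohort_csv),
                            cohort_config = default_config(),
                            seeds = list(cohort = 20201028L, split = 101L,
                                         clustering = 202L),
                            k_max = 10L, B = 100L, rule = "firstSEmax",
                            n_restarts = 25L, ratio = c(3, 1),
                            decimals = 2L,
                            cutoffs = c(-3.610, -1.966, 0.697, 2.629),
                            threshold = 0, schema = default_schema()) {
  stopifnot(all(vapply(seeds, is.numeric, logical(1))))
  structure(
    list(out_dir = out_dir, cohort_csv = cohort_csv, visits_csv = visits_csv,
         simulate = simulate, cohort_config = cohort_config,
         seeds = lapply(seeds, as.integer),
         k_max = k_max, B = B, rule = rule, n_restarts = n_restarts,
         ratio = ratio, decimals = decimals, cutoffs = cutoffs,
         threshold = threshold, schema = schema),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Stages: cohort acquisition (simulation or CSV) -> completeness filter ->
#' clustering (standardize, PCA, gap statistic, k-means, semantic labels) ->
#' 3:1 split -> logistic score fit on the training set -> rounded score
#' weights -> validation evaluation (accuracy, sensitivity, specificity,
#' AUC) -> cutoff-bin PPVs -> LOCF + outcome regressions.  Writes per-stage
#' CSV/JSON artifacts under `config$out_dir` and returns the run report.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return A `pipeline_report` list with every stage result.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "),
                                           ...)
  out <- function(name) file.path(config$out_dir, name)
  schema <- config$schema

  # 1. cohort
  if (config$simulate) {
    say("stage cohort: simulating from config (seed ",
        config$seeds$cohort, ")")
    cc <- config$cohort_config
    cohort <- simulate_cohort(cc, seed = config$seeds$cohort, schema = schema)
    visits <- simulate_visits(cohort, cc, seed = config$seeds$cohort + 1L)
    write_cohort(cohort, out("cohort.csv"))
    write_visits(visits, out("visits.csv"))
  } else {
    say("stage cohort: reading ", config$cohort_csv)
    cohort <- read_cohort(config$cohort_csv, schema)
    visits <- if (!is.null(config$visits_csv)) read_visits(config$visits_csv)
              else NULL
  }

  # 2. completeness filter
  filt <- apply_completeness_filter(cohort, schema$name, schema)
  say("stage filter: kept ", nrow(filt$kept), ", excluded ",
      nrow(filt$excluded))
  cohort <- filt$kept

  # 3. clustering
  say("stage cluster: gap statistic (k = 1..", config$k_max,
      ", B = ", config$B, ") + k-means")
  clustering <- cluster_cohort(cohort, schema, seed = config$seeds$clustering,
                               k_max = config$k_max, B = config$B,
                               rule = config$rule,
                               n_restarts = config$n_restarts)
  say("stage cluster: chose k = ", clustering$gap$chosen_k)
  readr::write_csv(as.data.frame(clustering$gap), out("gap_table.csv"))
  readr::write_csv(
    tibble::tibble(patient_id = cohort$patient_id,
                   cluster = clustering$assignments),
    out("assignments.csv")
  )
  comparison <- compare_clusters(cohort, clustering$assignments, schema)
  readr::write_csv(comparison, out("cluster_comparison.csv"))

  # 4. split + score fit
  split <- split_train_validation(cohort, config$ratio, config$seeds$split)
  train_labels <- clustering$assignments[match(split$training$patient_id,
                                               cohort$patient_id)]
  valid_labels <- clustering$assignments[match(split$validation$patient_id,
                                               cohort$patient_id)]
  say("stage score: fitting logistic model on ", nrow(split$training),
      " training records")
  model <- fit_logistic(split$training, train_labels)
  weights <- weights_from_model(model, config$decimals)

  # 5. evaluation + bins on the validation set
  valid_scores <- cnv_score(split$validation, weights)
  evaluation <- evaluate_score(valid_scores, valid_labels, config$threshold)
  bins <- ppv_bins(valid_scores, valid_labels, config$cutoffs,
                   config$threshold)
  say("stage evaluate: accuracy ", round(evaluation$accuracy, 3),
      ", AUC ", round(evaluation$auc, 3))
  readr::write_csv(as.data.frame(bins), out("ppv_bins.csv"))

  # 6. outcomes
  outcomes <- NULL
  if (!is.null(visits)) {
    say("stage outcomes: LOCF + regression of logMAR change on score")
    all_scores <- cnv_score(cohort, weights)
    outcomes <- outcome_association(cohort, visits, all_scores)
    readr::write_csv(outcomes, out("outcome_regressions.csv"))
  }

  report <- list(
    n_input = nrow(filt$kept) + nrow(filt$excluded),
    n_analysed = nrow(cohort),
    n_excluded = nrow(filt$excluded),
    chosen_k = clustering$gap$chosen_k,
    n_components = clustering$n_components,
    gap_table = as.data.frame(clustering$gap),
    cluster_sizes = table(clustering$assignments),
    split_sizes = c(training = nrow(split$training),
                    validation = nrow(split$validation)),
    model = list(coefficients = model$coefficients, se = model$se,
                 or = model$or, p_value = model$p_value),
    weights = list(intercept = weights$intercept,
                   terms = as.data.frame(weights$terms)),
    evaluation = list(accuracy = evaluation$accuracy,
                      sensitivity = evaluation$sensitivity,
                      specificity = evaluation$specificity,
                      auc = evaluation$auc),
    bins = as.data.frame(bins),
    outcomes = if (!is.null(outcomes)) as.data.frame(outcomes),
    seeds = config$seeds
  )
  jsonlite::write_json(
    report[c("n_input", "n_analysed", "n_excluded", "chosen_k",
             "n_components", "split_sizes", "evaluation", "seeds")],
    out("report.json"), auto_unbox = TRUE, digits = NA
  )
  class(report) <- "pipeline_report"
  report
}

#' Gap-curve plot
#'
#' @param gap A `gap_result`.
#' @return A ggplot object: gap(k) with +/- s_k error bars and the chosen k.
#' @export
plot_gap <- function(gap) {
  df <- as.data.frame(gap)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gap - .data$se,
                                          ymax = .data$gap + .data$se)) +
    ggplot2::geom_vline(xintercept = gap$chosen_k, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = df$k) +
    ggplot2::labs(x = "number of clusters k", y = "gap(k)",
                  title = sprintf("Gap statistic (chosen k = %d)",
                                  gap$chosen_k)) +
    ggplot2::theme_minimal()
}

#' PC1 vs PC2 scatter of the clustered cohort
#'
#' @param clustering A `cnv_clustering` from [cluster_cohort()].
#' @return A ggplot object.
#' @export
plot_pc_scatter <- function(clustering) {
  df <- data.frame(
    pc1 = clustering$pca$scores[, 1L],
    pc2 = clustering$pca$scores[, 2L],
    cluster = clustering$assignments
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::labs(x = "principal component 1", y = "principal component 2",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
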