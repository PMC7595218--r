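# Patient data model: feature schema, CSV dialects, completeness filtering,
# and derived clinical quantities (Brinkman index, logMAR conversion).

#' Default 61-feature baseline phenotype schema
#'
#' The deep-phenotype analysis operates on 61 baseline characteristics per
#' patient: continuous ocular measurements (logMAR acuity, axial length in mm,
#' retinal and subfoveal choroidal thickness in micrometres, lesion size),
#' binary imaging and history flags (choroidal vascular hyperpermeability,
#' pachyvessels, reduced fundus tessellation, drusen types, CNV type, systemic
#' history), smoking exposure, and a block of auxiliary phenotype channels
#' (`aux_01` ... `aux_33`) standing in for the graded characteristics that are
#' configuration rather than constants.  Eye-level features are keyed
#' affected/fellow, and sex is coded male = 0, female = 1; downstream scoring
#' relies on both conventions.
#'
#' @param n_aux Number of auxiliary continuous phenotype channels appended to
#'   the named features (default 33, giving 61 features in total).
#' @return A tibble with columns `name`, `kind` (`"continuous"` or
#'   `"binary"`) and `unit`.
#' @export
#' @examples
#' nrow(default_schema())  # 61
default_schema <- function(n_aux = 33L) {
  named <- tibble::tribble(
    ~name,                          ~kind,        ~unit,
    "age",                          "continuous", "years",
    "sex",                          "binary",     "male=0/female=1",
    "logmar_affected",              "continuous", "logMAR",
    "logmar_fellow",                "continuous", "logMAR",
    "axial_length_affected",        "continuous", "mm",
    "axial_length_fellow",          "continuous", "mm",
    "retinal_thickness_affected",   "continuous", "um",
    "sfct_affected",                "continuous", "um",
    "sfct_fellow",                  "continuous", "um",
    "gld",                          "continuous", "um",
    "cvh_either",                   "binary",     "flag",
    "polyp_affected",               "binary",     "flag",
    "pachyvessel_either",           "binary",     "flag",
    "reduced_tessellation_either",  "binary",     "flag",
    "pseudodrusen_either",          "binary",     "flag",
    "drusen_a_either",              "binary",     "flag",
    "drusen_b_either",              "binary",     "flag",
    "drusen_c_either",              "binary",     "flag",
    "cnv_type1",                    "binary",     "flag",
    "cnv_type2",                    "binary",     "flag",
    "history_csc",                  "binary",     "flag",
    "history_htn",                  "binary",     "flag",
    "history_dm",                   "binary",     "flag",
    "history_hld",                  "binary",     "flag",
    "history_ci",                   "binary",     "flag",
    "history_mi",                   "binary",     "flag",
    "cigarettes_per_day",           "continuous", "count",
    "smoking_years",                "continuous", "years"
  )
  if (n_aux > 0L) {
    aux <- tibble::tibble(
      name = sprintf("aux_%02d", seq_len(n_aux)),
      kind = "continuous",
      unit = "z"
    )
    named <- rbind(named, aux)
  }
  stopifnot(!anyDuplicated(named$name))
  named
}

#' Read a phenotype cohort CSV
#'
#' One row per patient; columns are `patient_id` plus the schema feature
#' names (an optional `true_cluster` column carries the hidden generating
#' label of synthetic cohorts).  Empty cells are missing values; unparsable
#' numeric cells become `NA`, never silent zeros.
#'
#' @param path Path to a comma-separated, `.`-decimal, UTF-8 file.
#' @param schema Feature schema, see [default_schema()].
#' @return A tibble, one row per patient.
#' @export
read_cohort <- function(path, schema = default_schema()) {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path, call. = FALSE)
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(c("patient_id", schema$name), header)
  if (length(missing_cols) > 0L) {
    stop("cohort file is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  types <- readr::cols(
    patient_id = readr::col_character(),
    .default = readr::col_double()
  )
  if ("true_cluster" %in% header) {
    types$cols$true_cluster <- readr::col_character()
  }
  cohort <- readr::read_csv(path, col_types = types, na = c("", "NA"))
  if (anyDuplicated(cohort$patient_id)) {
    dup <- unique(cohort$patient_id[duplicated(cohort$patient_id)])
    stop("duplicate patient_id in cohort file: ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  cohort
}

#' Write a phenotype cohort CSV
#'
#' Missing values are serialized as empty cells.  Numbers are written with
#' the shortest round-trippable representation, so write-then-read is
#' lossless for finite values and missing markers.
#'
#' @param cohort Cohort tibble (see [read_cohort()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Read / write a longitudinal visit table
#'
#' Columns `patient_id`, `month`, `logmar`; one row per visit, months
#' increasing within patient, month 0 = baseline.
#'
#' @param path CSV path.
#' @return A tibble with columns `patient_id`, `month`, `logmar`.
#' @export
read_visits <- function(path) {
  if (!file.exists(path)) {
    stop("visit file not found: ", path, call. = FALSE)
  }
  readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      month = readr::col_integer(),
      logmar = readr::col_double()
    ),
    na = c("", "NA")
  )
}

#' @rdname read_visits
#' @param visits Visit tibble.
#' @export
write_visits <- function(visits, path) {
  readr::write_csv(visits, path, na = "")
  invisible(path)
}

#' Completeness filter: exclude records with any missing required field
#'
#' Mirrors the study-entry rule that records lacking any required baseline
#' measurement are excluded before analysis.  A record is excluded iff at
#' least one required feature is missing; the first missing feature (in
#' `required` order) is recorded as the exclusion reason.
#'
#' @param cohort Cohort tibble.
#' @param required Character vector of required feature names (default: the
#'   full schema).
#' @param schema Feature schema the cohort conforms to.
#' @return A list with `kept` (tibble) and `excluded` (tibble with an extra
#'   `reason` column naming the first missing feature).
#' @export
apply_completeness_filter <- function(cohort,
                                      required = schema$name,
                                      schema = default_schema()) {
  stopifnot(all(required %in% names(cohort)))
  if (length(required) == 0L) {
    return(list(kept = cohort, excluded = cohort[0, , drop = FALSE]))
  }
  miss <- is.na(as.matrix(cohort[, required, drop = FALSE]))
  first_missing <- apply(miss, 1L, function(row) {
    idx <- which(row)
    if (length(idx) == 0L) NA_character_ else required[idx[1L]]
  })
  drop <- !is.na(first_missing)
  excluded <- cohort[drop, , drop = FALSE]
  if (nrow(excluded) > 0L) {
    excluded$reason <- first_missing[drop]
  } else {
    excluded$reason <- character(0)
  }
  list(kept = cohort[!drop, , drop = FALSE], excluded = excluded)
}

#' Brinkman index of cumulative smoking exposure
#'
#' Cigarettes per day multiplied by years of smoking.
#'
#' @param cigarettes_per_day Non-negative count.
#' @param smoking_years Non-negative years.
#' @return The index, vectorized over the inputs.
#' @export
#' @examples
#' brinkman_index(20, 30)  # 600
brinkman_index <- function(cigarettes_per_day, smoking_years) {
  if (any(cigarettes_per_day < 0, na.rm = TRUE) ||
      any(smoking_years < 0, na.rm = TRUE)) {
    stop("Brinkman index requires non-negative inputs", call. = FALSE)
  }
  cigarettes_per_day * smoking_years
}

#' Convert decimal visual acuity to logMAR
#'
#' logMAR = -log10(decimal acuity); lower is better vision.
#'
#' @param decimal_acuity Positive decimal acuity (1.0 = 0.0 logMAR).
#' @return logMAR value(s).
#' @export
#' @examples
#' to_logmar(0.1)  # 1.0
to_logmar <- function(decimal_acuity) {
  if (any(decimal_acuity <= 0, na.rm = TRUE)) {
    stop("decimal acuity must be positive", call. = FALSE)
  }
  -log10(decimal_acuity)
}
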