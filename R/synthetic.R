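# Synthetic two-latent-class cohort generator.
#
# The study population is emulated as a two-component mixture: an AMD-type
# class (older, thin choroid, soft drusen) and a PNV-type class (younger,
# thick choroid, pachychoroid flags).  Per-class means/SDs and prevalences
# default to the published between-cluster comparison table so that every
# downstream stage (clustering, scoring, outcomes) is testable without the
# undeposited patient data.

#' Per-cluster generative profile
#'
#' @param label Cluster label, `"AMD-type"` or `"PNV-type"`.
#' @param n Number of patients to generate for this cluster.
#' @param continuous_params Named list, feature -> `c(mean, sd)` in native
#'   units.
#' @param binary_prevalences Named numeric vector of probabilities in
#'   `[0, 1]`.
#' @return A `cluster_profile` object.
#' @export
cluster_profile <- function(label, n, continuous_params, binary_prevalences) {
  stopifnot(label %in% c("AMD-type", "PNV-type"), n >= 0)
  sds <- vapply(continuous_params, function(p) p[[2L]], numeric(1))
  if (any(sds < 0)) stop("continuous sd must be >= 0", call. = FALSE)
  if (any(binary_prevalences < 0 | binary_prevalences > 1)) {
    stop("binary prevalences must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(label = label, n = as.integer(n),
         continuous_params = continuous_params,
         binary_prevalences = binary_prevalences),
    class = "cluster_profile"
  )
}

#' Cohort generation configuration
#'
#' @param profiles List of [cluster_profile()] objects with identical feature
#'   name sets.
#' @param seed Integer seed; the same config always generates the same
#'   cohort.
#' @param truncation_bounds Named list, feature -> `c(low, high)` physiologic
#'   bounds in native units (Gaussian draws are rejected outside them, so
#'   thicknesses can never be negative).
#' @param sfct_correlation Within-cluster correlation of affected- and
#'   fellow-eye subfoveal choroidal thickness (the two are strongly paired in
#'   real eyes); in `(-1, 1)`.
#' @param followup Visit-simulation parameters: `months` schedule,
#'   `change_mean` (per cluster, per post-baseline month, logMAR),
#'   `change_sd` (logMAR), and per-visit `dropout` probability.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(profiles, seed = 20201028L,
                          truncation_bounds = list(),
                          sfct_correlation = 0,
                          followup = default_followup()) {
  labels <- vapply(profiles, function(p) p$label, character(1))
  stopifnot(!anyDuplicated(labels))
  total_n <- sum(vapply(profiles, function(p) p$n, integer(1)))
  if (total_n <= 0L) stop("total cohort size must be positive", call. = FALSE)
  feat_sets <- lapply(profiles, function(p)
    sort(c(names(p$continuous_params), names(p$binary_prevalences))))
  if (length(unique(feat_sets)) != 1L) {
    stop("profiles must share one feature-name set", call. = FALSE)
  }
  for (b in truncation_bounds) {
    if (b[[1L]] >= b[[2L]]) stop("truncation bounds need low < high", call. = FALSE)
  }
  if (abs(sfct_correlation) >= 1) {
    stop("sfct_correlation must lie in (-1, 1)", call. = FALSE)
  }
  structure(
    list(profiles = profiles, seed = as.integer(seed),
         truncation_bounds = truncation_bounds,
         sfct_correlation = sfct_correlation,
         followup = followup),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_followup <- function() {
  list(
    months = c(0L, 3L, 12L),
    change_mean = list(
      "AMD-type" = c("3" = -0.04, "12" = -0.06),
      "PNV-type" = c("3" = -0.14, "12" = -0.12)
    ),
    change_sd = 0.25,
    dropout = 0.10
  )
}

#' Default study-condition configuration
#'
#' Two cluster profiles transcribed from the published between-cluster
#' baseline comparison: 289 AMD-type and 248 PNV-type patients (537 in
#' total), with every printed continuous mean/SD pair and binary prevalence.
#' Features of the 61-feature schema that are not individually printed get
#' neutral defaults shared across the two clusters, so cluster recovery
#' cannot depend on them.  Affected/fellow subfoveal choroidal thickness is
#' generated with within-cluster correlation 0.8, which reproduces the
#' bimodal pooled SFCT histogram in both eyes.
#'
#' @param schema Feature schema the cohort will conform to.
#' @param seed Integer seed stored in the config.
#' @return A [cohort_config()].
#' @export
default_config <- function(schema = default_schema(), seed = 20201028L) {
  # printed per-cluster continuous (mean, sd), native units
  cont_amd <- list(
    age                        = c(75.03, 7.87),
    logmar_affected            = c(0.377, 0.385),
    axial_length_affected      = c(23.83, 1.10),
    axial_length_fellow        = c(23.97, 1.13),
    retinal_thickness_affected = c(451.46, 230.42),
    sfct_affected              = c(194.56, 74.19),
    sfct_fellow                = c(194.24, 74.29)
  )
  cont_pnv <- list(
    age                        = c(70.87, 8.53),
    logmar_affected            = c(0.259, 0.324),
    axial_length_affected      = c(23.37, 1.01),
    axial_length_fellow        = c(23.46, 1.02),
    retinal_thickness_affected = c(346.11, 161.47),
    sfct_affected              = c(334.42, 93.65),
    sfct_fellow                = c(327.85, 88.01)
  )
  # printed per-cluster prevalences (counts / cluster size)
  bin_amd <- c(
    sex = 81 / 289, history_csc = 4 / 289, cvh_either = 18 / 289,
    polyp_affected = 127 / 289, pachyvessel_either = 80 / 289,
    reduced_tessellation_either = 33 / 289, pseudodrusen_either = 28 / 289,
    drusen_a_either = 82 / 289, drusen_b_either = 107 / 289,
    drusen_c_either = 56 / 289
  )
  bin_pnv <- c(
    sex = 69 / 248, history_csc = 24 / 248, cvh_either = 107 / 248,
    polyp_affected = 127 / 248, pachyvessel_either = 213 / 248,
    reduced_tessellation_either = 200 / 248, pseudodrusen_either = 1 / 248,
    drusen_a_either = 11 / 248, drusen_b_either = 177 / 248,
    drusen_c_either = 122 / 248
  )
  # unprinted features: neutral defaults shared across clusters
  shared_cont <- list(
    logmar_fellow      = c(0.10, 0.18),
    gld                = c(3200, 1600),
    cigarettes_per_day = c(9, 11),
    smoking_years      = c(18, 18)
  )
  shared_bin <- c(
    cnv_type1 = 0.75, cnv_type2 = 0.25,
    history_htn = 0.42, history_dm = 0.16, history_hld = 0.22,
    history_ci = 0.04, history_mi = 0.02
  )
  aux_names <- schema$name[grepl("^aux_", schema$name)]
  shared_aux <- stats::setNames(
    rep(list(c(0, 1)), length(aux_names)), aux_names
  )

  make_profile <- function(label, n, cont, bin) {
    cluster_profile(
      label, n,
      continuous_params = c(cont, shared_cont, shared_aux),
      binary_prevalences = c(bin, shared_bin)
    )
  }
  bounds <- list(
    age = c(30, 110),
    logmar_affected = c(-0.3, 3), logmar_fellow = c(-0.3, 3),
    axial_length_affected = c(18, 32), axial_length_fellow = c(18, 32),
    retinal_thickness_affected = c(1, Inf),
    sfct_affected = c(1, Inf), sfct_fellow = c(1, Inf),
    gld = c(1, Inf),
    cigarettes_per_day = c(0, Inf), smoking_years = c(0, Inf)
  )
  cohort_config(
    profiles = list(
      make_profile("AMD-type", 289L, cont_amd, bin_amd),
      make_profile("PNV-type", 248L, cont_pnv, bin_pnv)
    ),
    seed = seed,
    truncation_bounds = bounds,
    sfct_correlation = 0.8,
    followup = default_followup()
  )
}

# truncated-normal draws by rejection; exact truncation, not clamping
rtrunc_norm <- function(n, mean, sd, low = -Inf, high = Inf) {
  if (sd == 0) {
    if (mean < low || mean > high) {
      stop("degenerate draw outside truncation bounds", call. = FALSE)
    }
    return(rep(mean, n))
  }
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(1000L)) {
    bad <- which(x < low | x > high)
    if (length(bad) == 0L) return(x)
    x[bad] <- stats::rnorm(length(bad), mean, sd)
  }
  stop("truncation bounds too tight for rejection sampling", call. = FALSE)
}

# correlated pair of truncated normals (joint rejection)
rtrunc_binorm <- function(n, m1, s1, b1, m2, s2, b2, rho) {
  if (s1 == 0 || s2 == 0 || rho == 0) {
    return(cbind(rtrunc_norm(n, m1, s1, b1[1L], b1[2L]),
                 rtrunc_norm(n, m2, s2, b2[1L], b2[2L])))
  }
  draw <- function(m) {
    z1 <- stats::rnorm(m)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(m)
    cbind(m1 + s1 * z1, m2 + s2 * z2)
  }
  x <- draw(n)
  for (i in seq_len(1000L)) {
    bad <- which(x[, 1L] < b1[1L] | x[, 1L] > b1[2L] |
                 x[, 2L] < b2[1L] | x[, 2L] > b2[2L])
    if (length(bad) == 0L) return(x)
    x[bad, ] <- draw(length(bad))
  }
  stop("truncation bounds too tight for rejection sampling", call. = FALSE)
}

#' Simulate a phenotype cohort
#'
#' Draws each cluster's continuous features from (optionally correlated,
#' truncated) Gaussians in native units and each binary feature as Bernoulli,
#' per the profiles in `config`.  Records carry their hidden generating label
#' in `true_cluster` for recovery tests.  The same config and seed always
#' yield the identical cohort.
#'
#' @param config A [cohort_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @param schema Feature schema (defines column order).
#' @return A tibble: `patient_id`, the schema features, `true_cluster`.
#' @export
simulate_cohort <- function(config, seed = config$seed,
                            schema = default_schema()) {
  stopifnot(inherits(config, "cohort_config"))
  total_n <- sum(vapply(config$profiles, function(p) p$n, integer(1)))
  if (total_n <= 0L) stop("empty cohort: total n is zero", call. = FALSE)
  bounds <- function(feat) config$truncation_bounds[[feat]] %||% c(-Inf, Inf)

  with_seed(seed, {
    blocks <- lapply(config$profiles, function(profile) {
      n <- profile$n
      if (n == 0L) return(NULL)
      cols <- list()
      cont <- profile$continuous_params
      paired <- c("sfct_affected", "sfct_fellow")
      if (all(paired %in% names(cont)) && config$sfct_correlation != 0) {
        p1 <- cont[["sfct_affected"]]; p2 <- cont[["sfct_fellow"]]
        xy <- rtrunc_binorm(n, p1[1L], p1[2L], bounds("sfct_affected"),
                            p2[1L], p2[2L], bounds("sfct_fellow"),
                            config$sfct_correlation)
        cols[["sfct_affected"]] <- xy[, 1L]
        cols[["sfct_fellow"]] <- xy[, 2L]
        cont <- cont[setdiff(names(cont), paired)]
      }
      for (feat in names(cont)) {
        p <- cont[[feat]]
        b <- bounds(feat)
        cols[[feat]] <- rtrunc_norm(n, p[1L], p[2L], b[1L], b[2L])
      }
      for (feat in names(profile$binary_prevalences)) {
        cols[[feat]] <- stats::rbinom(n, 1L, profile$binary_prevalences[[feat]])
      }
      out <- tibble::as_tibble(cols)
      out$true_cluster <- profile$label
      out
    })
    cohort <- do.call(rbind, blocks)
    cohort <- cohort[, c(schema$name, "true_cluster")]
    cohort <- cbind(
      tibble::tibble(patient_id = sprintf("P%04d", seq_len(nrow(cohort)))),
      cohort
    )
    tibble::as_tibble(cohort)
  })
}

#' Simulate a follow-up visit series for one patient
#'
#' Baseline (month 0) is the patient's affected-eye logMAR; each scheduled
#' post-baseline visit adds the cluster's visual-acuity change (mean per
#' month, shared SD) and is dropped with the configured dropout probability.
#'
#' @param baseline_logmar Baseline affected-eye logMAR.
#' @param cluster Generating cluster label of the patient.
#' @param config A [cohort_config()] (its `followup` block is used).
#' @param seed Optional RNG seed.
#' @return A tibble with columns `month`, `logmar` (baseline always present).
#' @export
simulate_followup <- function(baseline_logmar, cluster, config, seed = NULL) {
  fu <- config$followup
  with_seed(seed, {
    months <- sort(unique(as.integer(fu$months)))
    stopifnot(0L %in% months)
    post <- months[months > 0L]
    mu <- fu$change_mean[[cluster]]
    logmar <- c(baseline_logmar,
                baseline_logmar + mu[as.character(post)] +
                  stats::rnorm(length(post), 0, fu$change_sd))
    keep <- c(TRUE, stats::runif(length(post)) >= fu$dropout)
    tibble::tibble(month = months[keep], logmar = unname(logmar[keep]))
  })
}

#' Simulate follow-up visits for a whole cohort
#'
#' @param cohort Cohort tibble from [simulate_cohort()] (needs
#'   `patient_id`, `logmar_affected`, `true_cluster`).
#' @param config A [cohort_config()].
#' @param seed RNG seed; defaults to `config$seed + 1`.
#' @return A visit tibble: `patient_id`, `month`, `logmar`.
#' @export
simulate_visits <- function(cohort, config, seed = config$seed + 1L) {
  stopifnot(all(c("patient_id", "logmar_affected", "true_cluster") %in%
                  names(cohort)))
  with_seed(seed, {
    per <- lapply(seq_len(nrow(cohort)), function(i) {
      v <- simulate_followup(cohort$logmar_affected[i],
                             cohort$true_cluster[i], config, seed = NULL)
      v$patient_id <- cohort$patient_id[i]
      v[, c("patient_id", "month", "logmar")]
    })
    do.call(rbind, per)
  })
}

#' Serialize / restore a cohort configuration as YAML
#'
#' Every profile field (label, n, per-feature means/SDs/prevalences), the
#' truncation bounds, the SFCT correlation and the follow-up block are
#' addressable in the YAML document.
#'
#' @param config A [cohort_config()].
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a [cohort_config()].
#' @export
write_config <- function(config, path) {
  doc <- list(
    seed = config$seed,
    sfct_correlation = config$sfct_correlation,
    truncation_bounds = lapply(config$truncation_bounds, as.numeric),
    followup = list(
      months = config$followup$months,
      # month -> value maps so the names survive YAML
      change_mean = lapply(config$followup$change_mean, as.list),
      change_sd = config$followup$change_sd,
      dropout = config$followup$dropout
    ),
    profiles = lapply(config$profiles, function(p) {
      list(label = p$label, n = p$n,
           continuous_params = lapply(p$continuous_params, as.numeric),
           binary_prevalences = as.list(p$binary_prevalences))
    })
  )
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  profiles <- lapply(doc$profiles, function(p) {
    cluster_profile(
      p$label, p$n,
      continuous_params = lapply(p$continuous_params, as.numeric),
      binary_prevalences = unlist(p$binary_prevalences)
    )
  })
  fu <- doc$followup
  fu$change_mean <- lapply(fu$change_mean, unlist)
  cohort_config(
    profiles = profiles, seed = doc$seed,
    truncation_bounds = lapply(doc$truncation_bounds, as.numeric),
    sfct_correlation = doc$sfct_correlation,
    followup = fu
  )
}
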