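# shared fixtures: small schemas, tiny cohorts, gaussian blobs

# minimal 2-cluster config: two continuous features + one binary flag,
# far-separated means so recovery is unambiguous
tiny_config <- function(n1 = 20L, n2 = 20L, sd = 1, prev = c(0.1, 0.9),
                        seed = 42L) {
  cohort_config(
    profiles = list(
      cluster_profile("AMD-type", n1,
                      continuous_params = list(sfct_affected = c(190, sd),
                                               sfct_fellow = c(195, sd),
                                               logmar_affected = c(0.38, 0.1 * (sd > 0))),
                      binary_prevalences = c(cvh_either = prev[1L])),
      cluster_profile("PNV-type", n2,
                      continuous_params = list(sfct_affected = c(330, sd),
                                               sfct_fellow = c(328, sd),
                                               logmar_affected = c(0.26, 0.1 * (sd > 0))),
                      binary_prevalences = c(cvh_either = prev[2L]))
    ),
    seed = seed,
    truncation_bounds = list(sfct_affected = c(1, Inf),
                             sfct_fellow = c(1, Inf)),
    sfct_correlation = 0.5
  )
}

tiny_schema <- function() {
  tibble::tibble(
    name = c("sfct_affected", "sfct_fellow", "logmar_affected", "cvh_either"),
    kind = c("continuous", "continuous", "continuous", "binary"),
    unit = c("um", "um", "logMAR", "flag")
  )
}

# isotropic gaussian blobs; returns list(points, labels)
make_blobs <- function(n_per, centers, sd = 1, seed = 1L) {
  set.seed(seed)
  k <- nrow(centers)
  pts <- do.call(rbind, lapply(seq_len(k), function(j) {
    matrix(stats::rnorm(n_per * ncol(centers), sd = sd),
           n_per, ncol(centers)) +
      matrix(centers[j, ], n_per, ncol(centers), byrow = TRUE)
  }))
  list(points = pts, labels = rep(seq_len(k), each = n_per))
}

# fraction of points assigned to their generating cluster, best label
# permutation (k = 2)
recovery_rate <- function(assign, truth) {
  tt <- table(assign, truth)
  max(sum(diag(tt)), sum(tt[cbind(1:2, 2:1)])) / sum(tt)
}

# the published validation-set bin counts (AMD then PNV per bin)
table4_scores_labels <- function() {
  mids <- c(-5, -2.5, -0.5, 1.5, 3.5)  # one representative score per bin
  n_amd <- c(21, 19, 29, 2, 0)
  n_pnv <- c(0, 2, 8, 25, 29)
  list(
    scores = c(rep(mids, n_amd), rep(mids, n_pnv)),
    labels = c(rep("AMD-type", sum(n_amd)), rep("PNV-type", sum(n_pnv)))
  )
}
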