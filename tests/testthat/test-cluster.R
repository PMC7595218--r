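test_that("standardization z-scores columns and flags constants", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  z <- standardize_features(x)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))  # sample sd of (1,2,3) is 1
  expect_equal(unname(z[, "b"]), c(0, 0, 0))
  expect_equal(unname(attr(z, "constant")), c(FALSE, TRUE))

  # idempotence on already-standardized data
  set.seed(1)
  y <- matrix(rnorm(60), 20, 3)
  z1 <- standardize_features(y)
  z2 <- standardize_features(z1)
  expect_equal(unclass(z2)[, ], unclass(z1)[, ], tolerance = 1e-12)

  expect_error(standardize_features(cbind(c(1, NA))), "missing")
})

test_that("PCA matches a brute-force eigendecomposition of the covariance", {
  set.seed(42)
  x <- matrix(rnorm(100), 20, 5)
  p <- fit_pca(x)
  ev_oracle <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(p$explained_variance, ev_oracle[seq_len(p$rank)],
               tolerance = 1e-10)
  # orthonormal loadings
  expect_equal(crossprod(p$loadings), diag(p$rank), tolerance = 1e-8,
               ignore_attr = TRUE)
  # variance ordering
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  # full-rank reconstruction identity
  recon <- p$scores %*% t(p$loadings) +
    matrix(p$center, nrow(x), ncol(x), byrow = TRUE)
  expect_equal(recon, x, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("collinear data yields a rank-deficient PCA", {
  t <- seq(0, 1, length.out = 10)
  x <- cbind(t, 2 * t + 3)  # exactly on a line
  p <- fit_pca(x)
  expect_equal(p$rank, 1L)
  expect_error(fit_pca(x[1, , drop = FALSE]), "at least 2")
})

test_that("within-cluster dispersion follows the pairwise definition", {
  # one cluster of two points at distance d: D_r = 2 d^2, W = d^2 / 2
  two <- rbind(c(0, 0), c(3, 4))  # d = 5
  expect_equal(within_dispersion(two, c(1L, 1L)), 12.5)
  expect_equal(within_dispersion(two, c(1L, 1L), method = "plain"), 2.5)
  expect_equal(within_dispersion(rbind(c(1, 1), c(1, 1)), c(1L, 1L)), 0)
  expect_error(within_dispersion(two, c(1L, 1L), k = 2L), "empty cluster")
})

test_that("within-cluster dispersion equals centroid sum-of-squares on random instances", {
  set.seed(7)
  for (rep in 1:5) {
    pts <- matrix(rnorm(24), 12, 2)
    assign <- sample(1:3, 12, replace = TRUE)
    assign[1:3] <- 1:3  # all clusters nonempty
    expect_equal(within_dispersion(pts, assign, k = 3L),
                 brute_wss(pts, assign), tolerance = 1e-10)
  }
})

test_that("k-means recovers well-separated blobs and honours trivial cases", {
  blobs <- make_blobs(30L, rbind(c(0, 0), c(10, 10)), sd = 1, seed = 3L)
  km <- kmeans_cluster(blobs$points, 2L, seed = 1L)
  expect_equal(recovery_rate(km$assignments, blobs$labels), 1.0)

  # k = n: every point its own centroid, inertia 0
  pts <- matrix(rnorm(10), 5, 2)
  kmn <- kmeans_cluster(pts, 5L, seed = 1L)
  expect_equal(kmn$inertia, 0)
  expect_equal(sort(unique(kmn$assignments)), 1:5)

  # k = 1: inertia equals the single-cluster dispersion
  km1 <- kmeans_cluster(pts, 1L, seed = 1L)
  expect_equal(km1$inertia, within_dispersion(pts, rep(1L, 5L)),
               tolerance = 1e-10)

  expect_error(kmeans_cluster(pts, 6L, seed = 1L), "exceed")
})

test_that("k-means is seed-deterministic and its inertia trace is nonincreasing", {
  set.seed(5)
  pts <- matrix(rnorm(400), 100, 4)
  a <- kmeans_cluster(pts, 4L, seed = 11L)
  b <- kmeans_cluster(pts, 4L, seed = 11L)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$inertia, b$inertia)
  for (s in 1:5) {
    km <- kmeans_cluster(pts, 3L, seed = s, n_restarts = 1L)
    expect_true(all(diff(km$inertia_trace) <= 1e-9))
    expect_lte(km$inertia, km$inertia_trace[1L])
  }
})

test_that("gap arrays satisfy the definitional identity and s_k >= 0", {
  blobs <- make_blobs(40L, rbind(c(0, 0), c(6, 6)), sd = 1, seed = 2L)
  g <- gap_statistic(blobs$points, k_max = 5L, B = 20L, seed = 4L)
  expect_equal(g$gap + g$log_wk, g$e_log_wk, tolerance = 1e-12)
  expect_true(all(g$s_k >= 0))
  expect_true(g$chosen_k %in% g$k_values)
  expect_equal(g$chosen_k, 2L)
  expect_error(gap_statistic(blobs$points, k_max = 1L, B = 5L), "k_max")
  expect_error(gap_statistic(blobs$points[1:3, ], k_max = 5L, B = 5L),
               "smaller than")
})

test_that("selection rules agree with the reference implementation on random gap curves", {
  skip_if_not_installed("cluster")
  set.seed(9)
  for (rep in 1:50) {
    gap <- cumsum(rnorm(8, 0, 0.3))
    se <- runif(8, 0.01, 0.3)
    expect_equal(
      pachycnv:::choose_gap_k(gap, se, "firstSEmax"),
      unname(cluster::maxSE(gap, se, method = "firstSEmax"))
    )
    expect_equal(
      pachycnv:::choose_gap_k(gap, se, "tibshirani2001"),
      unname(cluster::maxSE(gap, se, method = "Tibs2001SEmax"))
    )
  }
})

test_that("data dispersion curve log(W_k) matches clusGap on separable data", {
  skip_if_not_installed("cluster")
  blobs <- make_blobs(30L, rbind(c(0, 0), c(8, 0), c(0, 8)), sd = 0.5,
                      seed = 6L)
  g <- gap_statistic(blobs$points, k_max = 3L, B = 10L, seed = 1L,
                     n_restarts = 20L)
  ref <- cluster::clusGap(blobs$points, stats::kmeans, K.max = 3L, B = 10L,
                          d.power = 2, nstart = 20L, verbose = FALSE)
  # same data, same partitions: clusGap halves the ordered-pair dispersion,
  # a constant log(2) offset on the log scale (it cancels in the gap)
  expect_equal(g$log_wk, unname(ref$Tab[, "logW"]) + log(2), tolerance = 1e-6)
})

test_that("a single isotropic blob selects k = 1 in the large majority of seeds", {
  chosen <- vapply(1:20, function(s) {
    pts <- make_blobs(120L, rbind(c(0, 0)), sd = 1, seed = 100L + s)$points
    gap_statistic(pts, k_max = 5L, B = 30L, seed = s)$chosen_k
  }, integer(1))
  expect_gte(mean(chosen == 1L), 0.7)
})

test_that("the clustered cohort recovers the generating structure and direction of effects", {
  cfg <- default_config()
  cohort <- simulate_cohort(cfg, seed = 77L)
  cl <- cluster_cohort(cohort, seed = 7L, B = 30L)
  expect_equal(cl$gap$chosen_k, 2L)
  expect_equal(sort(unique(cl$assignments)), c("AMD-type", "PNV-type"))

  pnv <- cl$assignments == "PNV-type"
  amd <- cl$assignments == "AMD-type"
  # direction of effects: thicker choroid and more CVH in the PNV-type cluster
  expect_gt(mean(cohort$sfct_fellow[pnv]), mean(cohort$sfct_fellow[amd]))
  expect_gt(mean(cohort$cvh_either[pnv]), mean(cohort$cvh_either[amd]))
  # label recovery against the hidden generating labels
  expect_gte(mean(cl$assignments == cohort$true_cluster), 0.95)
})

test_that("a cohort of identical records is rejected as degenerate", {
  cohort <- simulate_cohort(tiny_config(n1 = 6L, n2 = 0L, sd = 0,
                                        prev = c(0, 0)),
                            schema = tiny_schema())
  expect_error(cluster_cohort(cohort, schema = tiny_schema(), B = 5L),
               "degenerate")
})

test_that("the partition is invariant to input row order", {
  blobs <- make_blobs(40L, rbind(c(0, 0, 0), c(9, 9, 9), c(-9, 9, -9)),
                      sd = 1, seed = 13L)
  ids <- sprintf("P%03d", seq_len(nrow(blobs$points)))
  km1 <- kmeans_cluster(blobs$points, 3L, seed = 10L)
  set.seed(20)
  perm <- sample(length(ids))
  km2 <- kmeans_cluster(blobs$points[perm, ], 3L, seed = 10L)
  part1 <- split(ids, km1$assignments)
  part2 <- split(ids[perm], km2$assignments)
  norm <- function(p) unname(lapply(p[order(vapply(p, min, character(1)))], sort))
  expect_equal(norm(part1), norm(part2))
})

test_that("cluster comparison reproduces the published CVH contrast and the Fisher oracle", {
  # CVH row: 18/289 positives vs 107/248
  cvh <- c(rep(1, 18), rep(0, 271), rep(1, 107), rep(0, 141))
  lab <- c(rep("AMD-type", 289), rep("PNV-type", 248))
  sfct <- c(rnorm(289, 194, 74), rnorm(248, 328, 88))
  cohort <- tibble::tibble(cvh_either = cvh, sfct_fellow = sfct)
  schema <- tibble::tibble(name = c("cvh_either", "sfct_fellow"),
                           kind = c("binary", "continuous"),
                           unit = c("flag", "um"))
  tab <- compare_clusters(cohort, lab, schema)
  expect_lt(tab$p_value[tab$feature == "cvh_either"], 0.0001)
  expect_lt(tab$p_value[tab$feature == "sfct_fellow"], 0.0001)
  expect_equal(tab$`stat_AMD-type`[1L], 18)
  expect_equal(tab$`stat_PNV-type`[1L], 107)

  # identical groups with equal counts: p = 1
  same <- tibble::tibble(cvh_either = rep(c(0, 1), 20))
  lab2 <- rep(c("AMD-type", "PNV-type"), each = 20)
  schema2 <- schema[1, ]
  expect_equal(compare_clusters(same, lab2, schema2)$p_value, 1)

  # small 2x2 equals exhaustive hypergeometric enumeration
  small <- tibble::tibble(cvh_either = c(rep(1, 3), rep(0, 7),
                                         rep(1, 7), rep(0, 3)))
  lab3 <- rep(c("AMD-type", "PNV-type"), each = 10)
  expect_equal(compare_clusters(small, lab3, schema2)$p_value,
               fisher_enum(3, 7, 7, 3), tolerance = 1e-10)

  expect_error(compare_clusters(same, rep("AMD-type", 40), schema2),
               "two groups")
})
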