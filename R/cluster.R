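# Unsupervised stage: standardization, PCA, within-cluster dispersion,
# k-means (k-means++/Lloyd), gap-statistic choice of k, semantic labeling of
# the clusters, and the per-feature cluster comparison table.

#' Z-score a feature matrix column-wise
#'
#' Each column is centred by its mean and scaled by its sample (n-1) standard
#' deviation.  Constant columns cannot be scaled; they are mapped to all
#' zeros and flagged.  The per-column statistics are kept as attributes
#' (`center`, `scale`, `constant`) so the same transform can be reused.
#'
#' @param x Numeric matrix, no missing values (filter first).
#' @return The standardized matrix with attributes `center`, `scale`,
#'   `constant`.
#' @export
standardize_features <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values in feature matrix; filter first", call. = FALSE)
  ctr <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  constant <- !is.finite(sds) | sds < 1e-12
  scl <- ifelse(constant, 1, sds)
  z <- sweep(sweep(x, 2L, ctr, `-`), 2L, scl, `/`)
  z[, constant] <- 0
  structure(z, center = ctr, scale = scl, constant = constant)
}

#' Principal component analysis of a standardized feature matrix
#'
#' Loadings are the eigenvectors of the sample covariance matrix, ordered by
#' explained variance; components with eigenvalues below `1e-10` times the
#' largest are dropped as numerically null, so one exact linear dependency
#' among p features yields p - 1 retained components.
#'
#' @param x Numeric matrix (n x p), typically from
#'   [standardize_features()].
#' @return A `pca_model`: `loadings` (p x r, orthonormal),
#'   `explained_variance` (length r, nonincreasing), `rank`, `scores`
#'   (n x r), `center`.
#' @export
fit_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least 2 observations", call. = FALSE)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  if (ev[1L] < 1e-300) {
    r <- 0L
  } else {
    r <- sum(ev > 1e-10 * ev[1L])
  }
  structure(
    list(
      loadings = pr$rotation[, seq_len(r), drop = FALSE],
      explained_variance = ev[seq_len(r)],
      rank = r,
      scores = pr$x[, seq_len(r), drop = FALSE],
      center = pr$center
    ),
    class = "pca_model"
  )
}

#' Within-cluster dispersion W_k
#'
#' For each cluster r with n_r points, D_r is the sum over all ordered
#' within-cluster pairs of squared Euclidean distances, and
#' W_k = sum_r D_r / (2 n_r) — algebraically identical to the within-cluster
#' sum of squares about the centroids.  `method = "plain"` sums unsquared
#' distances instead (a looser reading of "sum of the pairwise distance",
#' exposed for comparison, never used by the gap machinery).
#'
#' @param points Numeric matrix (n x r).
#' @param assignments Integer/character cluster labels, length n.
#' @param k Optional expected number of clusters; if any of `1..k` is empty
#'   the partition is rejected as degenerate.
#' @param method `"squared"` (default) or `"plain"`.
#' @return Scalar W_k.
#' @export
within_dispersion <- function(points, assignments, k = NULL,
                              method = c("squared", "plain")) {
  method <- match.arg(method)
  points <- as.matrix(points)
  stopifnot(nrow(points) == length(assignments))
  if (!is.null(k)) {
    sizes <- tabulate(as.integer(assignments), nbins = k)
    if (any(sizes == 0L)) {
      stop("degenerate partition: empty cluster", call. = FALSE)
    }
  }
  w <- 0
  for (cl in unique(assignments)) {
    p <- points[assignments == cl, , drop = FALSE]
    n_r <- nrow(p)
    if (n_r < 2L) next  # D_r = 0
    d <- stats::dist(p)
    d_r <- if (method == "squared") 2 * sum(d^2) else 2 * sum(d)
    w <- w + d_r / (2 * n_r)
  }
  w
}

#' K-means clustering (k-means++ initialization, Lloyd iterations)
#'
#' Runs `n_restarts` independent k-means++ initializations followed by Lloyd
#' descent and keeps the solution with the smallest inertia (within-cluster
#' sum of squares).  Empty clusters arising during descent are re-seeded at
#' the point farthest from its current centre.  Deterministic given `seed`.
#'
#' @param points Numeric matrix (n x r).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param n_restarts Number of random restarts (default 25).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @param tol Relative inertia-change convergence tolerance (default 1e-6).
#' @return A `kmeans_result`: `assignments` (1-based), `centroids` (k x r),
#'   `inertia`, `n_iter`, `inertia_trace`, `seed`, `n_restarts`.
#' @export
kmeans_cluster <- function(points, k, seed = NULL, n_restarts = 25L,
                           max_iter = 300L, tol = 1e-6) {
  x <- as.matrix(points)
  if (k > nrow(x)) stop("k must not exceed the number of points", call. = FALSE)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  with_seed(seed, {
    best <- .kmeans_cpp(x, as.integer(k), as.integer(n_restarts),
                        as.integer(max_iter), tol)
    structure(
      list(assignments = best$assignments, centroids = best$centers,
           inertia = best$inertia, n_iter = best$n_iter,
           inertia_trace = best$inertia_trace,
           seed = seed, n_restarts = n_restarts, k = k),
      class = "kmeans_result"
    )
  })
}

# log W_k on one dataset for each k in 1..k_max
log_wk_curve <- function(x, k_max, n_restarts, max_iter, tol) {
  n <- nrow(x)
  ctr <- colMeans(x)
  w <- numeric(k_max)
  w[1L] <- sum(sweep(x, 2L, ctr, `-`)^2)
  for (k in seq_len(k_max)[-1L]) {
    w[k] <- kmeans_cluster(x, k, seed = NULL, n_restarts = n_restarts,
                           max_iter = max_iter, tol = tol)$inertia
  }
  log(w)
}

# k chosen from the gap curve by a 1-standard-error rule
choose_gap_k <- function(gap, se, rule = c("firstSEmax", "tibshirani2001")) {
  rule <- match.arg(rule)
  kk <- length(gap)
  if (kk == 1L) return(1L)
  if (rule == "firstSEmax") {
    decr <- diff(gap) <= 0
    nc <- if (any(decr)) which.max(decr) else kk  # first local maximum
    candidates <- which(gap[seq_len(nc)] >= gap[nc] - se[nc])
    candidates[1L]
  } else {
    ok <- which(gap[-kk] >= gap[-1L] - se[-1L])
    if (length(ok) == 0L) kk else ok[1L]
  }
}

#' Gap statistic for choosing the number of clusters
#'
#' For each candidate k the within-cluster dispersion W_k of the data is
#' compared with its expectation under a structureless reference null:
#' gap(k) = E*\[log W_k\] - log W_k.  The reference is B datasets drawn
#' uniformly over the bounding box of the data in its principal-component
#' rotation (`"pca_box"`, the recommended null; `"axis_box"` uses the raw
#' axis-aligned box).  s_k is the reference SD of log W_k* times
#' sqrt(1 + 1/B).  The default `"firstSEmax"` rule picks the smallest k whose
#' gap is within one s_k of the first local maximum of the gap curve;
#' `"tibshirani2001"` picks the smallest k with gap(k) >= gap(k+1) - s_(k+1).
#'
#' @param points Numeric matrix (n x r), e.g. PCA scores.
#' @param k_max Largest candidate k (k = 1..k_max), must be < n.
#' @param B Number of reference datasets (default 100).
#' @param seed Integer seed for the reference draws and k-means restarts.
#' @param rule Selection rule (see above).
#' @param reference `"pca_box"` or `"axis_box"`.
#' @param n_restarts K-means restarts per dispersion evaluation (default 5;
#'   the gap machinery runs (B+1) x k_max k-means fits).
#' @param max_iter,tol Passed to [kmeans_cluster()].
#' @return A `gap_result`: `k_values`, `log_wk`, `e_log_wk`, `gap`, `s_k`,
#'   `chosen_k`, `B`, `rule`.
#' @export
gap_statistic <- function(points, k_max = 10L, B = 100L, seed = NULL,
                          rule = c("firstSEmax", "tibshirani2001"),
                          reference = c("pca_box", "axis_box"),
                          n_restarts = 5L, max_iter = 100L, tol = 1e-6) {
  rule <- match.arg(rule)
  reference <- match.arg(reference)
  x <- as.matrix(points)
  n <- nrow(x)
  if (k_max < 2L) stop("k_max must be at least 2", call. = FALSE)
  if (B < 1L) stop("B must be at least 1", call. = FALSE)
  if (k_max >= n) stop("k_max must be smaller than the number of points", call. = FALSE)

  with_seed(seed, {
    log_wk <- log_wk_curve(x, k_max, n_restarts, max_iter, tol)

    xc <- sweep(x, 2L, colMeans(x), `-`)
    if (reference == "pca_box") {
      v <- svd(xc, nu = 0L)$v
      xp <- xc %*% v
    } else {
      v <- NULL
      xp <- xc
    }
    lo <- apply(xp, 2L, min)
    hi <- apply(xp, 2L, max)

    log_wk_star <- matrix(NA_real_, B, k_max)
    for (b in seq_len(B)) {
      zp <- sapply(seq_along(lo), function(j) stats::runif(n, lo[j], hi[j]))
      z <- if (is.null(v)) zp else zp %*% t(v)
      log_wk_star[b, ] <- log_wk_curve(z, k_max, n_restarts, max_iter, tol)
    }
    e_log_wk <- colMeans(log_wk_star)
    s_k <- apply(log_wk_star, 2L, stats::sd) * sqrt(1 + 1 / B)
    gap <- e_log_wk - log_wk
    structure(
      list(k_values = seq_len(k_max), log_wk = log_wk, e_log_wk = e_log_wk,
           gap = gap, s_k = s_k,
           chosen_k = choose_gap_k(gap, s_k, rule),
           B = as.integer(B), rule = rule, reference = reference),
      class = "gap_result"
    )
  })
}

#' @export
as.data.frame.gap_result <- function(x, ...) {
  data.frame(k = x$k_values, log_wk = x$log_wk, e_log_wk = x$e_log_wk,
             gap = x$gap, se = x$s_k)
}

#' @export
print.gap_result <- function(x, ...) {
  cat("Gap statistic (B =", x$B, ", rule =", x$rule, ")\n")
  print(as.data.frame(x), digits = 4)
  cat("chosen k:", x$chosen_k, "\n")
  invisible(x)
}

#' Cluster a phenotype cohort end to end
#'
#' Encodes the schema features of each record, standardizes them, projects
#' onto all principal components of numerical rank, chooses the number of
#' clusters by the gap statistic, runs k-means at the chosen k on the
#' retained component scores, and labels the clusters semantically: the
#' cluster with the larger mean fellow-eye subfoveal choroidal thickness is
#' the PNV-type (pachychoroid) cluster, the thinner one the AMD-type
#' cluster (exact ties are an error, never a silent choice).
#'
#' @param cohort Cohort tibble with complete values for every schema
#'   feature.
#' @param schema Feature schema, see [default_schema()].
#' @param seed Integer seed driving the gap reference draws and k-means.
#' @param k_max,B,rule Passed to [gap_statistic()].
#' @param n_restarts Restarts for the final k-means fit (default 25).
#' @param gap_restarts Restarts inside the gap machinery (default 5).
#' @return A `cnv_clustering` list: `pca` (`pca_model`), `gap`
#'   (`gap_result`), `kmeans` (`kmeans_result`), `labeling` (cluster index ->
#'   semantic label), `assignments` (per-patient semantic labels),
#'   `n_components`.
#' @export
cluster_cohort <- function(cohort, schema = default_schema(), seed = 1L,
                           k_max = 10L, B = 100L,
                           rule = c("firstSEmax", "tibshirani2001"),
                           n_restarts = 25L, gap_restarts = 5L) {
  rule <- match.arg(rule)
  x <- as.matrix(cohort[, schema$name])
  if (anyNA(x)) stop("cohort has missing feature values; filter first", call. = FALSE)
  z <- standardize_features(x)
  pca <- fit_pca(z)
  if (pca$rank == 0L) {
    stop("degenerate cohort: no feature variation to cluster", call. = FALSE)
  }
  gap <- gap_statistic(pca$scores, k_max = k_max, B = B, seed = seed,
                       rule = rule, n_restarts = gap_restarts)
  km <- kmeans_cluster(pca$scores, k = gap$chosen_k, seed = seed + 1L,
                       n_restarts = n_restarts)
  labeling <- label_clusters(cohort$sfct_fellow, km$assignments, gap$chosen_k)
  structure(
    list(pca = pca, gap = gap, kmeans = km, labeling = labeling,
         assignments = unname(labeling[km$assignments]),
         n_components = pca$rank),
    class = "cnv_clustering"
  )
}

# semantic labels from mean fellow-eye SFCT per cluster
label_clusters <- function(sfct_fellow, assignments, k) {
  means <- vapply(seq_len(k), function(cl) {
    mean(sfct_fellow[assignments == cl])
  }, numeric(1))
  if (anyDuplicated(means)) {
    stop("cluster labeling is ambiguous: tied mean fellow-eye SFCT", call. = FALSE)
  }
  labels <- character(k)
  if (k == 2L) {
    labels[which.max(means)] <- "PNV-type"
    labels[which.min(means)] <- "AMD-type"
  } else {
    labels[order(means)] <- sprintf("cluster_%d", seq_len(k))
  }
  stats::setNames(labels, seq_len(k))
}

#' Per-feature comparison between two labeled clusters
#'
#' Continuous features: mean and SD per group, two-sided Wilcoxon rank-sum
#' p-value.  Binary features: count and percentage per group, two-sided
#' Fisher exact p-value.
#'
#' @param cohort Cohort tibble.
#' @param assignments Character vector of group labels, one per record (two
#'   distinct labels, both nonempty).
#' @param schema Feature schema.
#' @return A tibble: `feature`, `kind`, per-group summary columns and
#'   `p_value`.
#' @export
compare_clusters <- function(cohort, assignments, schema = default_schema()) {
  groups <- sort(unique(assignments))
  if (length(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  g1 <- assignments == groups[1L]
  g2 <- assignments == groups[2L]
  if (!any(g1) || !any(g2)) stop("degenerate comparison: empty group", call. = FALSE)
  rows <- lapply(seq_len(nrow(schema)), function(i) {
    feat <- schema$name[i]
    x <- cohort[[feat]]
    if (schema$kind[i] == "binary") {
      tab <- rbind(c(sum(x[g1] == 1), sum(x[g1] == 0)),
                   c(sum(x[g2] == 1), sum(x[g2] == 0)))
      p <- stats::fisher.test(tab)$p.value
      tibble::tibble(
        feature = feat, kind = "binary",
        stat1 = sum(x[g1] == 1), stat2 = sum(x[g2] == 1),
        spread1 = 100 * mean(x[g1] == 1), spread2 = 100 * mean(x[g2] == 1),
        p_value = p
      )
    } else {
      p <- stats::wilcox.test(x[g1], x[g2], exact = FALSE)$p.value
      tibble::tibble(
        feature = feat, kind = "continuous",
        stat1 = mean(x[g1]), stat2 = mean(x[g2]),
        spread1 = stats::sd(x[g1]), spread2 = stats::sd(x[g2]),
        p_value = p
      )
    }
  })
  out <- do.call(rbind, rows)
  # stat_<group>: mean (continuous) or positive count (binary);
  # spread_<group>: sd or percent positive
  names(out) <- c("feature", "kind",
                  paste0("stat_", groups[1L]), paste0("stat_", groups[2L]),
                  paste0("spread_", groups[1L]), paste0("spread_", groups[2L]),
                  "p_value")
  out
}
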