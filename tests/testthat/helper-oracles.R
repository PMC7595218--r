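# independent brute-force oracles, kept free of the implementation paths

# within-cluster sum of squares about centroids, computed directly
brute_wss <- function(points, assign) {
  sum(vapply(unique(assign), function(cl) {
    p <- points[assign == cl, , drop = FALSE]
    ctr <- colMeans(p)
    sum(sweep(p, 2L, ctr, `-`)^2)
  }, numeric(1)))
}

# AUC as the Mann-Whitney concordance probability, ties half-weighted
auc_concordance <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  grid <- expand.grid(p = pos, n = neg)
  mean(ifelse(grid$p > grid$n, 1, ifelse(grid$p == grid$n, 0.5, 0)))
}

# two-sided Fisher exact p by exhaustive hypergeometric tail summation
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# OLS coefficients and SEs straight from the normal equations
ols_normal_eq <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (nrow(X) - ncol(X))
  list(beta = drop(beta), se = sqrt(diag(xtx_inv) * s2))
}

# mean of a Gaussian truncated to [low, high]
truncnorm_mean <- function(mean, sd, low = -Inf, high = Inf) {
  if (sd == 0) return(mean)
  a <- (low - mean) / sd
  b <- (high - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# maximised log-likelihood of a two-component univariate Gaussian mixture
# (plain EM), and of the single-Gaussian MLE, for bimodality checks
mixture_logliks <- function(x, iter = 200L) {
  ll1 <- sum(dnorm(x, mean(x), sqrt(mean((x - mean(x))^2)), log = TRUE))
  q <- quantile(x, c(0.25, 0.75))
  mu <- as.numeric(q); s <- rep(sd(x) / 2, 2); pi1 <- 0.5
  for (i in seq_len(iter)) {
    d1 <- pi1 * dnorm(x, mu[1], s[1])
    d2 <- (1 - pi1) * dnorm(x, mu[2], s[2])
    g <- d1 / (d1 + d2)
    pi1 <- mean(g)
    mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
    s <- sqrt(c(sum(g * (x - mu[1])^2) / sum(g),
                sum((1 - g) * (x - mu[2])^2) / sum(1 - g)))
  }
  ll2 <- sum(log(pi1 * dnorm(x, mu[1], s[1]) +
                   (1 - pi1) * dnorm(x, mu[2], s[2])))
  list(one = ll1, two = ll2)
}
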