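# Independent oracles used to cross-check the implementation.

# Brute-force inversion of the +/- 3 SD truncated-normal CDF by bisection.
oracle_truncnorm_ppf <- function(q, a, b, tol = 1e-12) {
  mu <- (a + b) / 2
  sigma <- (b - a) / 6
  cdf <- function(x) {
    (pnorm((x - mu) / sigma) - pnorm(-3)) / (pnorm(3) - pnorm(-3))
  }
  lo <- a
  hi <- b
  while (hi - lo > tol * sigma) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < q) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Numerical moments of the +/- 3 SD truncated normal by quadrature.
oracle_truncnorm_var <- function(a, b) {
  mu <- (a + b) / 2
  sigma <- (b - a) / 6
  z <- pnorm(3) - pnorm(-3)
  dens <- function(x) dnorm((x - mu) / sigma) / (sigma * z)
  stats::integrate(function(x) (x - mu)^2 * dens(x), a, b,
                   rel.tol = 1e-10)$value
}

# Dense midpoint-rule integral of an analytic field against the uniform
# density over the orientation rectangle.
oracle_dense_integral <- function(f, nx = 600, ny = 300) {
  ax <- seq(-30, 30, length.out = nx + 1)
  by <- seq(0, 30, length.out = ny + 1)
  amid <- (ax[-1] + ax[-(nx + 1)]) / 2
  bmid <- (by[-1] + by[-(ny + 1)]) / 2
  g <- expand.grid(a = amid, b = bmid)
  mean(f(g$a, g$b))
}

# Exhaustive pair-counting AUC (ties count one half).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Exact Mann-Whitney one-sided p-value by enumeration of group
# assignments (small samples, no ties).
oracle_mw_p_less <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  combs <- utils::combn(length(pooled), n1)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_all <- apply(combs, 2, function(ix) {
    a <- pooled[ix]
    b <- pooled[-ix]
    sum(outer(a, b, ">"))
  })
  mean(u_all <= u_obs)
}

# Shared small fixtures
tiny_cohort <- function(n = 6, seed = 7, M = 33, label_N = 500) {
  generate_cohort(cohort_config(n_subjects = n, label_N = label_N, M = M),
                  seed = seed)
}
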