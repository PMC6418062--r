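test_that("truncated-normal quantiles match a brute-force CDF inversion", {
  s <- trunc_spec(60, 120)
  expect_equal(truncnorm_ppf(0.5, s), 90)
  expect_equal(truncnorm_ppf(1e-12, s), 60, tolerance = 1e-6)
  expect_equal(truncnorm_ppf(1 - 1e-12, s), 120, tolerance = 1e-6)
  for (q in c(0.05, 0.25, 0.8413, 0.99)) {
    expect_equal(truncnorm_ppf(q, s), oracle_truncnorm_ppf(q, 60, 120),
                 tolerance = 1e-8)
  }
  # strictly increasing in q
  qs <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(truncnorm_ppf(qs, s)) > 0))
  expect_error(truncnorm_ppf(0, s), "inside")
  expect_error(truncnorm_ppf(1.2, s), "inside")
})

test_that("Latin-hypercube sampling stratifies every column", {
  s <- lh_sample(10, list(x = trunc_spec(60, 120)), seed = 3)
  # exactly one draw per decile of the truncated distribution
  q <- truncnorm_ppf(seq(0.1, 0.9, by = 0.1), trunc_spec(60, 120))
  strata <- findInterval(s$matrix[, 1], q)
  expect_setequal(strata, 0:9)
  # multi-column: each column stratified independently
  s6 <- lh_sample(50, fall_model_default(), seed = 5)
  for (j in 1:6) {
    spec <- fall_model_default()[[j]]
    edges <- truncnorm_ppf(seq(0.02, 0.98, by = 0.02), spec)
    expect_setequal(findInterval(s6$matrix[, j], edges), 0:49)
  }
  expect_error(lh_sample(1, list(x = trunc_spec(0, 1)), seed = 1), "at least 2")
})

test_that("Latin-hypercube draws are reproducible and substreams are stable", {
  a <- lh_sample(100, fall_model_default(), seed = 17)
  b <- lh_sample(100, fall_model_default(), seed = 17)
  expect_identical(a$matrix, b$matrix)
  c <- lh_sample(100, fall_model_default(), seed = 18)
  expect_false(identical(a$matrix, c$matrix))
  # dropping the last column must not change the first columns' draws
  d <- lh_sample(100, fall_model_default()[1:3], seed = 17)
  expect_identical(a$matrix[, 1:3], d$matrix)
})

test_that("LH sample moments converge to the truncated-normal moments", {
  spec <- trunc_spec(-2.55, 0.914)
  errs <- sapply(c(1e2, 1e3, 1e4), function(n) {
    e <- lh_moment_errors(spec, n, seed = 29)
    max(e$eps_mu, e$eps_sigma)
  })
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 1e-3)
})

test_that("Iman-Conover induces rank correlation without touching marginals", {
  specs <- list(m = trunc_spec(24.15, 103.35), H = trunc_spec(1.394, 1.766))
  s <- lh_sample(1e4, specs, seed = 31)
  target <- matrix(c(1, 0.429, 0.429, 1), 2)
  out <- iman_conover(s, target, seed = 32)
  expect_lt(abs(cor(out$matrix, method = "spearman")[1, 2] - 0.429), 0.02)
  # marginal multisets unchanged
  expect_equal(sort(out$matrix[, 1]), sort(s$matrix[, 1]))
  expect_equal(sort(out$matrix[, 2]), sort(s$matrix[, 2]))
  # identity target leaves columns near-independent
  id <- iman_conover(s, diag(2), seed = 33)
  expect_lt(abs(cor(id$matrix, method = "spearman")[1, 2]), 0.03)
  # invalid targets rejected
  bad <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_error(iman_conover(s, bad, seed = 1), "positive definite")
})

test_that("stratified uniforms match an independent LHS implementation", {
  # same stratification contract as lhs::randomLHS: one point per stratum
  set.seed(40)
  ref <- lhs::randomLHS(50, 1)
  ours <- lh_sample(50, list(x = unif_spec(0, 1)), seed = 40)$matrix[, 1]
  expect_setequal(findInterval(ref[, 1], seq(0.02, 0.98, by = 0.02)),
                  findInterval(ours, seq(0.02, 0.98, by = 0.02)))
})
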