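test_that("Saltelli estimator recovers analytic indices of an additive model", {
  specs <- list(x1 = unif_spec(0, 1), x2 = unif_spec(0, 1))
  s <- saltelli_first_order(function(x) x[, 1] + 2 * x[, 2], specs,
                            N = 2e4, seed = 90)
  expect_lt(abs(unname(s$indices["x1"]) - 0.2), 0.03)
  expect_lt(abs(unname(s$indices["x2"]) - 0.8), 0.03)
  # single-input model
  s1 <- saltelli_first_order(function(x) 3 * x[, 1], specs, N = 5e3, seed = 91)
  expect_lt(abs(unname(s1$indices["x1"]) - 1), 0.05)
  expect_lt(abs(unname(s1$indices["x2"])), 0.05)
  # constant model: all indices zero by convention
  s0 <- saltelli_first_order(function(x) rep(5, nrow(x)), specs,
                             N = 1e3, seed = 92)
  expect_equal(unname(s0$indices), c(0, 0))
  # non-finite outputs are reported with the offending input
  expect_error(
    saltelli_first_order(function(x) ifelse(x[, 1] > 0.5, NaN, 1), specs,
                         N = 100, seed = 93),
    "non-finite")
})

test_that("correlated-input estimator is consistent with Saltelli when independent", {
  specs <- list(x1 = unif_spec(0, 1), x2 = unif_spec(0, 1))
  model <- function(x) x[, 1] + 2 * x[, 2]
  cs <- correlated_first_order(model, specs, diag(2), N = 1e4, seed = 94)
  expect_lt(abs(unname(cs$indices["x1"]) - 0.2), 0.03)
  expect_lt(abs(unname(cs$indices["x2"]) - 0.8), 0.03)
  # correlation leaks variance into an input the model never reads
  corr <- matrix(c(1, 0.9, 0.9, 1), 2)
  cl <- correlated_first_order(function(x) x[, 1], specs, corr,
                               N = 1e4, seed = 95)
  expect_gt(unname(cl$indices["x2"]), 0.5)
  expect_lt(abs(unname(cl$indices["x1"]) - 1), 0.05)
})

test_that("sensitivity screening selects the smallest prefix reaching the threshold", {
  expect_equal(select_sensitive(c(m = 0.660, theta_f = 0.146, eta_P = 0.106)),
               c("m", "theta_f"))   # 0.806 >= 0.8
  expect_equal(select_sensitive(c(x = 0.9)), "x")
  # deterministic alphabetical tie-break
  expect_equal(select_sensitive(c(y = 0.5, x = 0.5)), c("x", "y"))
  expect_error(select_sensitive(c(a = 0, b = -0.1)), "positive")
  expect_warning(out <- select_sensitive(c(a = 0.3, b = 0.2)), "less than")
  expect_equal(out, c("a", "b"))
})

test_that("uncertainty band reproduces its closed form and symmetries", {
  # impact-force band: mass and final-angle uncertainty, radian convention
  b1 <- uncertainty_band(c(m = 4.10, theta_f = 3.70), 3650, 809,
                         c(101, 30), c(31.0, -30),
                         angular = c(FALSE, TRUE))
  expect_equal(signif(b1$s_tilde, 3), 166)
  # skeletal-force band: mass and impact-attenuation uncertainty
  b2 <- uncertainty_band(c(m = 4.10, eta_I = 0.342), 5040, 277,
                         c(66.0, -2.55), c(31.0, 0.568))
  expect_equal(signif(b2$s_tilde, 3), 558)
  # swapping the extrema labels leaves the band unchanged
  b3 <- uncertainty_band(c(m = 4.10, eta_I = 0.342), 277, 5040,
                         c(31.0, 0.568), c(66.0, -2.55))
  expect_equal(b3$s_tilde, b2$s_tilde)
  # zero input uncertainty propagates to a zero band
  b4 <- uncertainty_band(c(m = 0, eta_I = 0), 5040, 277,
                         c(66.0, -2.55), c(31.0, 0.568))
  expect_equal(b4$s_tilde, 0)
  expect_error(uncertainty_band(c(1), 10, 5, c(2), c(2)), "coincide")
})

test_that("bin extrema recover the conditional structure of a known model", {
  set.seed(96)
  n <- 2e4
  X <- cbind(a = runif(n, 0, 10), b = runif(n, -5, 5))
  Y <- 3 * X[, "a"] + rnorm(n, sd = 0.1)
  bx <- bin_extrema(Y, X, bins = 10)
  # extrema lie in the outer bins of the active coordinate (bin centres)
  expect_equal(bx$X_max[1], 9.5, tolerance = 0.05)
  expect_equal(bx$X_min[1], 0.5, tolerance = 0.05)
  expect_equal(bx$Y_max, 3 * 9.5, tolerance = 0.3)
  expect_equal(bx$Y_min, 3 * 0.5, tolerance = 0.3)
  expect_error(bin_extrema(Y, X[-1, ]), "match")
})
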