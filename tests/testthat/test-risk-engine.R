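test_that("fracture indicator is inclusive at the strength boundary", {
  expect_equal(fracture_indicator(2500, 2000), 1L)
  expect_equal(fracture_indicator(1500, 2000), 0L)
  expect_equal(fracture_indicator(2000, 2000), 1L)   # F >= S, inclusive
  expect_equal(fracture_indicator(c(1, 3), c(2, 2)), c(0L, 1L))
  expect_error(fracture_indicator(-1, 2000), "non-negative")
  expect_error(fracture_indicator(1, 0), "positive")
})

test_that("per-fall fracture probability hits its degenerate limits", {
  g <- build_orientation_grid(33)
  subj <- list(m = 63.75, H = 1.58)
  unbreakable <- strength_surface("u", g, rep(1e6, 33))
  expect_equal(fall_fracture_probability(subj, unbreakable, N = 200, seed = 1), 0)
  brittle <- strength_surface("b", g, rep(1, 33))
  expect_equal(fall_fracture_probability(subj, brittle, N = 200, seed = 1), 1)
})

test_that("degenerate fall distributions reduce P to a single indicator", {
  # near-point-mass fall parameters: one deterministic outcome
  eps <- 1e-9
  fm <- list(theta_i = trunc_spec(15 - eps, 15 + eps),
             theta_f = trunc_spec(90 - eps, 90 + eps),
             v_i = trunc_spec(0.7 - eps, 0.7 + eps),
             a_i = trunc_spec(2.55 - eps, 2.55 + eps),
             eta_P = trunc_spec(0.65 - eps, 0.65 + eps),
             eta_I = trunc_spec(-0.818 - eps, -0.818 + eps))
  subj <- list(m = 63.75, H = 1.58)
  F0 <- fall_forces(63.75, 1.58,
                    cbind(theta_i = 15, theta_f = 90, v_i = 0.7, a_i = 2.55,
                          eta_P = 0.65, eta_I = -0.818))$F
  g <- build_orientation_grid(4)
  above <- strength_surface("a", g, rep(F0 + 1, 4))
  below <- strength_surface("b", g, rep(F0 - 1, 4))
  expect_equal(fall_fracture_probability(subj, above, fm, N = 50, seed = 2), 0)
  expect_equal(fall_fracture_probability(subj, below, fm, N = 50, seed = 2), 1)
})

test_that("both integration orders of P agree (Fubini equivalence)", {
  g <- build_orientation_grid(33)
  subj <- list(m = 70, H = 1.62)
  surf <- synthesize_surface("f", 2600, g, c(1, -0.5, 0.3, 0.8, -1))
  N <- 2000
  falls <- lh_sample(N, fall_model_default(), seed = 60)$matrix
  F <- fall_forces(subj$m, subj$H, falls)$F
  # order 1: average the indicator over falls, then quadrature
  chi_bar <- vapply(surf$values, function(s) mean(F >= s), numeric(1))
  p1 <- integrate_field(chi_bar, g)
  # order 2: quadrature per fall, then Monte Carlo mean
  p2 <- mean(vapply(seq_len(N), function(j) {
    integrate_field(as.numeric(F[j] >= surf$values), g)
  }, numeric(1)))
  expect_lt(abs(p1 - p2), 1e-12)
  # and the engine's own value equals order 1
  expect_equal(fall_fracture_probability(subj, surf, N = N, seed = 60), p1,
               tolerance = 1e-14)
})

test_that("ARF0 conversion matches the binomial closed form and is monotone", {
  expect_equal(round(arf0_from_p(0.03, 0.65), 2), 1.96)
  expect_equal(arf0_from_p(0, 0.65), 0)
  expect_equal(arf0_from_p(1, 0.65), 100)
  expect_equal(arf0_from_p(0.10, 0.65), 100 * (1 - 0.9^0.65), tolerance = 1e-12)
  expect_equal(round(arf0_from_p(0.10, 0.65), 2), 6.62)
  # monotone in P and in the fall rate
  expect_true(all(diff(arf0_from_p(seq(0, 1, by = 0.1), 0.65)) > 0))
  expect_gt(arf0_from_p(0.3, 1.0), arf0_from_p(0.3, 0.65))
  expect_error(arf0_from_p(1.2, 0.65), "\\[0, 1\\]")
})

test_that("P responds monotonically to strength and mass scaling", {
  g <- build_orientation_grid(33)
  surf <- synthesize_surface("m", 2400, g, c(0.5, 0.5, 0, -0.2, 0.1))
  subj <- list(m = 63.75, H = 1.58)
  p_base <- fall_fracture_probability(subj, surf, N = 1000, seed = 61)
  # uniformly stronger bone: P cannot increase
  strong <- strength_surface("s", g, surf$values * 1.5)
  expect_lte(fall_fracture_probability(subj, strong, N = 1000, seed = 61),
             p_base)
  # heavier body, same bone: P cannot decrease, within the mass range
  # where m (1 - eta_ST(BMI)) still grows (below the soft-tissue
  # turnover near 72 kg at this height the force is increasing in mass)
  light <- list(m = 50, H = 1.58)
  expect_lte(fall_fracture_probability(light, surf, N = 1000, seed = 61),
             p_base)
})

test_that("cohort runs are deterministic and tolerate missing surfaces", {
  coh <- tiny_cohort(n = 4, seed = 71, label_N = 200)
  r1 <- run_cohort(coh$subjects, coh$surfaces, N = 500, seed = 5)
  r2 <- run_cohort(coh$subjects, coh$surfaces, N = 500, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$P >= 0 & r1$P <= 1))
  expect_true(all(r1$ARF0_percent >= 0 & r1$ARF0_percent <= 100))
  # identical subject + identical seed gives identical P
  id <- coh$subjects$subject_id[1]
  subj <- list(m = coh$subjects$mass_kg[1], H = coh$subjects$height_m[1])
  expect_identical(
    fall_fracture_probability(subj, coh$surfaces[[id]], N = 500, seed = 9),
    fall_fracture_probability(subj, coh$surfaces[[id]], N = 500, seed = 9))
  # a missing surface yields NA for that subject and a warning, not an abort
  expect_warning(
    r3 <- run_cohort(coh$subjects, coh$surfaces[-2], N = 200, seed = 5),
    coh$subjects$subject_id[2])
  expect_true(is.na(r3$ARF0_percent[2]))
  expect_false(anyNA(r3$ARF0_percent[-2]))
})
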