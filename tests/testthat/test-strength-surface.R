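test_that("orientation grids use the documented lattice layouts", {
  g4 <- build_orientation_grid(4)
  expect_equal(g4$M, 4)
  expect_setequal(paste(g4$points[, 1], g4$points[, 2]),
                  c("-30 0", "30 0", "-30 30", "30 30"))
  expect_equal(nrow(g4$triangles), 2)
  g33 <- build_orientation_grid(33)
  expect_equal(sort(unique(g33$points[, "alpha_deg"])), seq(-30, 30, by = 6))
  expect_equal(sort(unique(g33$points[, "beta_deg"])), c(0, 15, 30))
  g231 <- build_orientation_grid(231)
  expect_equal(g231$M, 231)
  expect_error(build_orientation_grid(50), "unsupported")
})

test_that("triangulations cover the rectangle exactly for every supported M", {
  for (M in c(4, 15, 33, 66, 231)) {
    g <- build_orientation_grid(M)
    areas <- apply(g$triangles, 1, function(tr) {
      p <- g$points[tr, ]
      abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
            (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
    })
    expect_equal(sum(areas), 1800)
    expect_equal(sum(g$weights), 1)
    expect_true(all(g$weights > 0))
    expect_true(all(g$points[, 1] >= -30 & g$points[, 1] <= 30))
    expect_true(all(g$points[, 2] >= 0 & g$points[, 2] <= 30))
  }
})

test_that("field integration is exact for linear fields and matches a dense oracle", {
  g <- build_orientation_grid(33)
  expect_equal(integrate_field(rep(0.2, 33), g), 0.2)
  # odd linear field integrates to zero
  expect_equal(integrate_field(g$points[, "alpha_deg"] / 30, g), 0,
               tolerance = 1e-14)
  # any linear field is integrated exactly
  lin <- function(a, b) 1.5 + 0.02 * a - 0.03 * b
  expect_equal(integrate_field(lin(g$points[, 1], g$points[, 2]), g),
               oracle_dense_integral(lin), tolerance = 1e-6)
  # smooth field against the dense midpoint-rule oracle on the finest grid
  smooth <- function(a, b) {
    2 + 0.2 * sin(pi * a / 60) + 0.1 * cos(pi * b / 30) +
      0.15 * (a / 30) * (b / 30)
  }
  g231 <- build_orientation_grid(231)
  got <- integrate_field(smooth(g231$points[, 1], g231$points[, 2]), g231)
  ref <- oracle_dense_integral(smooth)
  expect_lt(abs(got - ref) / abs(ref), 1e-3)
  expect_error(integrate_field(rep(1, 10), g), "does not match")
})

test_that("indicator integral is monotone in the force threshold", {
  g <- build_orientation_grid(33)
  set.seed(50)
  vals <- 2000 + 800 * runif(33)
  surf <- strength_surface("s", g, vals)
  Fs <- seq(1500, 3500, by = 100)
  p <- vapply(Fs, function(f) integrate_field(as.numeric(f >= surf$values), g),
              numeric(1))
  expect_true(all(diff(p) >= 0))
})

test_that("surface statistics and constructors validate and summarise", {
  g <- build_orientation_grid(4)
  s <- strength_surface("a", g, rep(3000, 4))
  st <- surface_stats(s)
  expect_equal(unlist(st), c(S_min = 3000, S_max = 3000, S_mean = 3000))
  s2 <- strength_surface("b", g, c(1000, 2000, 3000, 2000))
  expect_equal(surface_stats(s2)$S_min, 1000)
  expect_equal(surface_stats(s2)$S_max, 3000)
  expect_equal(surface_stats(s2)$S_mean, 2000)
  expect_error(strength_surface("c", g, c(-1, 1, 1, 1)), "positive")
  expect_error(strength_surface("d", g, rep(1, 3)), "length")
})

test_that("synthetic surfaces have unit-mean shape and honour degenerate limits", {
  g <- build_orientation_grid(33)
  s <- synthesize_surface("x", 2800, g, rep(0, 5))
  expect_equal(mean(s$values), 2800, tolerance = 1e-10)
  # zero shape variance: every subject identical up to scale, so perfectly
  # correlated with the population mean surface
  s2 <- synthesize_surface("y", 1400, g, rep(0, 5))
  expect_equal(cor(s$values, s2$values), 1)
  # excessive amplitude drives the shape negative and is rejected
  expect_error(synthesize_surface("z", 2800, g, c(3, 3, 3, 3, 3), amp = 10),
               "non-positive")
  expect_error(synthesize_surface("w", 2800, g, rep(0, 4)), "length 5")
})

test_that("strength CSV round-trips and validates grid completeness", {
  g <- build_orientation_grid(15)
  surfs <- list(A = synthesize_surface("A", 2500, g, c(1, 0, -1, 0.5, 0)),
                B = synthesize_surface("B", 3100, g, c(0, 1, 0, -0.5, 1)))
  f1 <- tempfile(fileext = ".csv")
  write_strength_csv(surfs, f1)
  back <- read_strength_csv(f1)
  expect_named(back, c("A", "B"))
  expect_equal(back$A$values, surfs$A$values, tolerance = 1e-8)
  # second write is byte-identical
  f2 <- tempfile(fileext = ".csv")
  write_strength_csv(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a missing orientation row is reported with the subject id
  df <- read.csv(f1)
  write.csv(df[-2, ], f1, row.names = FALSE, quote = FALSE)
  expect_error(read_strength_csv(f1), "A")
})
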