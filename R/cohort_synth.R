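#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of a 98-subject
#' case-control validation cohort of postmenopausal women: per-group
#' anthropometric means/SDs, weak rank correlations between mass, height
#' and orientation-averaged femoral strength, and a surrogate strength
#' model calibrated so the cohort ARF0 distribution spans roughly 2-82%
#' with a median near 36%. Anthropometrics are pooled across the two
#' groups before sampling, mirroring a cohort pair-matched for age,
#' weight and height, and truncated at +/- 3 SD.
#'
#' @param n_subjects Cohort size (default 98, half per group).
#' @param m_stats,H_stats,age_stats Two-row matrices (fracture /
#'   non-fracture group) of mean and SD for mass (kg), height (m), age
#'   (yr).
#' @param rank_corr Target Spearman correlations, named numeric:
#'   `r_mH`, `r_mS`, `r_HS`.
#' @param strength_mean,strength_sd Population mean/SD of
#'   orientation-averaged strength (N).
#' @param strength_bounds Truncation bounds of mean strength (N).
#' @param shape_amp Per-subject anisotropy perturbation amplitude.
#' @param M Orientation grid size for the surfaces (default 33).
#' @param label_N Latin-hypercube falls used for the labelling risk pass.
#' @return List of class `arf_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 98,
                          m_stats = rbind(fracture = c(62.6, 14.3),
                                          non_fracture = c(64.9, 12.1)),
                          H_stats = rbind(fracture = c(1.58, 0.0653),
                                          non_fracture = c(1.58, 0.0592)),
                          age_stats = rbind(fracture = c(75.4, 9.44),
                                            non_fracture = c(74.7, 8.86)),
                          rank_corr = c(r_mH = 0.429, r_mS = 0.264,
                                        r_HS = 0.294),
                          strength_mean = 2800, strength_sd = 1000,
                          strength_bounds = c(390, 6330),
                          shape_amp = 0.08, M = 33, label_N = 2000) {
  if (any(m_stats[, 2] <= 0) || any(H_stats[, 2] <= 0) ||
      any(age_stats[, 2] <= 0)) {
    stop("group SDs must be strictly positive")
  }
  if (n_subjects < 2) stop("cohort must contain at least 2 subjects")
  cfg <- list(n_subjects = n_subjects, m_stats = m_stats, H_stats = H_stats,
              age_stats = age_stats, rank_corr = rank_corr,
              strength_mean = strength_mean, strength_sd = strength_sd,
              strength_bounds = strength_bounds, shape_amp = shape_amp,
              M = M, label_N = label_N)
  # feasibility of the correlation structure
  C <- .cohort_corr_matrix(rank_corr)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("target rank-correlation matrix is not positive definite")
  structure(cfg, class = "arf_cohort_config")
}

.cohort_corr_matrix <- function(rc) {
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- rc[["r_mH"]]
  C[1, 3] <- C[3, 1] <- rc[["r_mS"]]
  C[2, 3] <- C[3, 2] <- rc[["r_HS"]]
  C
}

# pooled mean and SD over the two groups (equal sizes)
.pooled <- function(stats2) {
  c(mean = mean(stats2[, 1]), sd = sqrt(mean(stats2[, 2]^2)))
}

#' Generate a synthetic validation cohort
#'
#' Draws correlated anthropometrics and mean strengths (+/- 3 SD
#' truncated normals via Latin-hypercube sampling, rank correlations
#' induced by Iman-Conover), synthesises a strength surface per subject,
#' runs the multiscale risk model once, and assigns fracture labels by a
#' Bernoulli mechanism with probability given by each subject's ARF0,
#' rebalanced to exactly half cases by ARF0-weighted resampling. The
#' labels are a synthetic stand-in for clinical fracture status: they
#' guarantee an imperfect but tunable classification signal.
#'
#' @param config An [cohort_config()].
#' @param seed Integer root seed.
#' @param constants [fixed_constants()].
#' @param fall_model Named list of six fall-parameter specs.
#' @return List of class `arf_cohort`: `subjects` (data frame:
#'   `subject_id, group, fracture_label, mass_kg, height_m, age_yr`),
#'   `surfaces` (named list), `risk` (the labelling [run_cohort()]
#'   output) and `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            constants = fixed_constants(),
                            fall_model = fall_model_default()) {
  stopifnot(inherits(config, "arf_cohort_config"))
  n <- config$n_subjects
  m_p <- .pooled(config$m_stats)
  H_p <- .pooled(config$H_stats)
  age_p <- .pooled(config$age_stats)
  specs <- list(
    m = trunc_spec(m_p["mean"] - 3 * m_p["sd"], m_p["mean"] + 3 * m_p["sd"]),
    H = trunc_spec(H_p["mean"] - 3 * H_p["sd"], H_p["mean"] + 3 * H_p["sd"]),
    S = unif_spec(0, 1)
  )
  s <- lh_sample(n, specs, seed)
  s <- iman_conover(s, .cohort_corr_matrix(config$rank_corr),
                    seed = .column_seed(seed, 17L))
  draws <- s$matrix
  # map the rank-correlated uniform strength column through the
  # asymmetrically truncated normal (monotone, so ranks are preserved)
  zlo <- stats::pnorm((config$strength_bounds[1] - config$strength_mean) /
                        config$strength_sd)
  zhi <- stats::pnorm((config$strength_bounds[2] - config$strength_mean) /
                        config$strength_sd)
  S_mean <- config$strength_mean + config$strength_sd *
    stats::qnorm(zlo + draws[, "S"] * (zhi - zlo))
  age_spec <- trunc_spec(age_p["mean"] - 3 * age_p["sd"],
                         age_p["mean"] + 3 * age_p["sd"])
  age <- lh_sample(n, list(age = age_spec), .column_seed(seed, 23L))$matrix[, 1]

  grid <- build_orientation_grid(config$M)
  coef_rng <- .substream(.column_seed(seed, 29L))
  surfaces <- vector("list", n)
  ids <- sprintf("S%03d", seq_len(n))
  for (i in seq_len(n)) {
    zc <- pmin(pmax(coef_rng$rnorm(5), -3), 3)
    surfaces[[i]] <- synthesize_surface(ids[i], S_mean[i], grid, zc,
                                        amp = config$shape_amp)
  }
  names(surfaces) <- ids

  subjects <- data.frame(subject_id = ids, group = NA_character_,
                         fracture_label = NA_integer_,
                         mass_kg = draws[, "m"], height_m = draws[, "H"],
                         age_yr = age, stringsAsFactors = FALSE)
  risk <- run_cohort(subjects, surfaces, fall_model, N = config$label_N,
                     seed = .column_seed(seed, 37L), constants = constants)
  p <- risk$ARF0_percent / 100
  lab_rng <- .substream(.column_seed(seed, 41L))
  labels <- as.integer(lab_rng$runif(n) < p)
  # rebalance to exactly n/2 cases: promote controls with weight p,
  # demote cases with weight 1 - p
  target <- floor(n / 2)
  with_seed_sample <- function(pool, k, w) {
    u <- lab_rng$runif(length(pool))
    pool[order(u^(1 / pmax(w, 1e-12)), decreasing = TRUE)][seq_len(k)]
  }
  if (sum(labels) > target) {
    demote <- with_seed_sample(which(labels == 1), sum(labels) - target,
                               (1 - p)[labels == 1])
    labels[demote] <- 0L
  } else if (sum(labels) < target) {
    promote <- with_seed_sample(which(labels == 0), target - sum(labels),
                                p[labels == 0])
    labels[promote] <- 1L
  }
  subjects$fracture_label <- labels
  subjects$group <- ifelse(labels == 1, "fracture", "non-fracture")
  structure(list(subjects = subjects, surfaces = surfaces, risk = risk,
                 seed = as.integer(seed)),
            class = "arf_cohort")
}

#' Write a cohort to CSV files
#'
#' @param cohort An `arf_cohort` (or a list with `subjects`, `surfaces`).
#' @param cohort_path Path of the subject table CSV
#'   (`subject_id, group, fracture_label, mass_kg, height_m, age_yr`).
#' @param strength_path Path of the long-format strength CSV.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, cohort_path, strength_path) {
  utils::write.csv(cohort$subjects[, c("subject_id", "group",
                                       "fracture_label", "mass_kg",
                                       "height_m", "age_yr")],
                   cohort_path, row.names = FALSE, quote = FALSE)
  write_strength_csv(cohort$surfaces, strength_path)
  invisible(c(cohort = cohort_path, strength = strength_path))
}

#' Read a cohort from CSV files
#'
#' @param cohort_path,strength_path Paths written by [write_cohort()].
#' @return List with `subjects` and `surfaces`.
#' @export
read_cohort <- function(cohort_path, strength_path) {
  subjects <- utils::read.csv(cohort_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "mass_kg", "height_m")
  if (!all(need %in% names(subjects))) {
    stop(sprintf("cohort CSV %s must contain columns: %s",
                 cohort_path, paste(need, collapse = ", ")))
  }
  surfaces <- read_strength_csv(strength_path)
  list(subjects = subjects, surfaces = surfaces)
}
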