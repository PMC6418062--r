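#' Latin-hypercube moment errors against truncated-normal theory
#'
#' Normalised errors of a finite LH sample's mean and variance against
#' the truncated distribution's theoretical moments:
#' `eps_mu = |mu* - mu| / sigma` and
#' `eps_sigma = |sigma*^2 - sigma^2| / sigma^2`, where `mu`, `sigma^2`
#' are the truncated-normal moments (not the untruncated ones; comparing
#' against the untruncated variance leaves a floor of about 0.027, the
#' +/- 3 SD truncation deficit).
#'
#' @param spec A [trunc_spec()].
#' @param N Sample size.
#' @param seed Integer seed.
#' @return List with `eps_mu`, `eps_sigma`, `N`, `seed`.
#' @export
lh_moment_errors <- function(spec, N, seed = 1L) {
  mom <- truncated_moments(spec)
  x <- lh_sample(N, list(x = spec), seed)$matrix[, 1]
  list(eps_mu = abs(mean(x) - mom$mu_trunc) / sqrt(mom$var_trunc),
       eps_sigma = abs(stats::var(x) - mom$var_trunc) / mom$var_trunc,
       N = as.integer(N), seed = as.integer(seed))
}

#' Orientation-quadrature refinement study
#'
#' Evaluates a subject's ARF0 on a ladder of orientation grids against a
#' reference grid, holding the Monte Carlo falls fixed (common random
#' numbers), so that the reported errors isolate the quadrature
#' approximation. Requires the strength surface as an analytic function
#' of orientation so every grid can be populated exactly; synthetic
#' surfaces satisfy this.
#'
#' @param subj List with `m`, `H` (an [subject()] works).
#' @param surface_fun Function `(alpha_deg, beta_deg) -> strength (N)`,
#'   vectorised.
#' @param fall_model Named list of six fall-parameter specs.
#' @param M_list Grid sizes to assess (default `c(4, 15, 33, 66)`).
#' @param ref_M Reference grid size (default 231).
#' @param N Latin-hypercube sample size (default 1e4).
#' @param seed Integer seed (shared by all grids).
#' @param constants [fixed_constants()].
#' @return Data frame with columns `M`, `ARF0_percent`,
#'   `error_pp` (absolute difference to the reference ARF0, percentage
#'   points); the reference row carries error 0 by definition.
#' @export
quadrature_convergence <- function(subj, surface_fun,
                                   fall_model = fall_model_default(),
                                   M_list = c(4, 15, 33, 66), ref_M = 231,
                                   N = 1e4, seed = 1L,
                                   constants = fixed_constants()) {
  Ms <- c(M_list, ref_M)
  arf <- vapply(Ms, function(M) {
    grid <- build_orientation_grid(M)
    vals <- surface_fun(grid$points[, "alpha_deg"], grid$points[, "beta_deg"])
    surf <- strength_surface("refine", grid, vals)
    P <- fall_fracture_probability(subj, surf, fall_model, N = N,
                                   seed = seed, constants = constants)
    arf0_from_p(P, constants$n_fall)
  }, numeric(1))
  ref <- arf[length(arf)]
  data.frame(M = Ms, ARF0_percent = arf, error_pp = abs(arf - ref))
}

#' Monte Carlo convergence of cohort ARF0
#'
#' For each LH sample size in `N_list`, re-runs the cohort and reports
#' the median and maximum absolute ARF0 deviation (percentage points)
#' from an independently seeded reference run at `ref_N`.
#'
#' @param subjects,surfaces As in [run_cohort()].
#' @param fall_model Named list of six fall-parameter specs.
#' @param N_list Sample sizes to assess.
#' @param M Orientation count of the surfaces (informational).
#' @param ref_N Reference sample size; must exceed `max(N_list)`.
#' @param seed Root seed; the reference run uses a distinct substream.
#' @param constants [fixed_constants()].
#' @return Data frame with columns `N`, `median_err_pp`, `max_err_pp`.
#' @export
mc_convergence <- function(subjects, surfaces,
                           fall_model = fall_model_default(),
                           N_list = c(1e2, 1e3, 1e4), M = 33, ref_N = 1e5,
                           seed = 1L, constants = fixed_constants()) {
  if (ref_N <= max(N_list)) stop("ref_N must exceed every entry of N_list")
  ref <- run_cohort(subjects, surfaces, fall_model, N = ref_N,
                    seed = .column_seed(seed, 999983L),
                    constants = constants)$ARF0_percent
  res <- lapply(seq_along(N_list), function(i) {
    arf <- run_cohort(subjects, surfaces, fall_model, N = N_list[i],
                      seed = .column_seed(seed, i),
                      constants = constants)$ARF0_percent
    err <- abs(arf - ref)
    data.frame(N = N_list[i],
               median_err_pp = stats::median(err, na.rm = TRUE),
               max_err_pp = max(err, na.rm = TRUE))
  })
  do.call(rbind, res)
}
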