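#' Fracture indicator of a single fall
#'
#' `chi = 1` when the attenuated impact force reaches or exceeds the
#' femoral strength at the realised impact orientation (`F >= S`,
#' inclusive), else 0.
#'
#' @param F Attenuated impact force (N, >= 0). Vectorised.
#' @param S Femoral strength (N, > 0).
#' @return Integer 0/1 vector.
#' @export
fracture_indicator <- function(F, S) {
  if (any(F < 0)) stop("impact force must be non-negative")
  if (any(S <= 0)) stop("strength must be strictly positive")
  as.integer(F >= S)
}

#' Impact forces for a set of realised falls
#'
#' Chains the body-floor impact model and the ground-skeleton
#' force-transfer model: kinetic energy, hip impact velocity, unattenuated
#' peak force and attenuated force on the greater trochanter.
#'
#' @param m,H Body mass (kg) and height (m); scalars or per-fall vectors.
#' @param falls Matrix (or data frame) with columns
#'   `theta_i, theta_f, v_i, a_i, eta_P, eta_I` — one row per fall.
#' @param constants [fixed_constants()].
#' @param eta_ST Passive soft-tissue attenuation; derived from BMI when
#'   `NULL` (requires scalar or per-fall `m`, `H`).
#' @return List with per-fall vectors `e`, `u`, `F_star`, `F`.
#' @export
fall_forces <- function(m, H, falls, constants = fixed_constants(),
                        eta_ST = NULL) {
  falls <- as.matrix(falls)
  need <- c("theta_i", "theta_f", "v_i", "a_i", "eta_P", "eta_I")
  if (!all(need %in% colnames(falls))) {
    stop(sprintf("falls must contain columns: %s", paste(need, collapse = ", ")))
  }
  e <- kinetic_energy(H, falls[, "theta_i"], falls[, "theta_f"],
                      falls[, "v_i"], falls[, "a_i"], constants)
  u <- impact_velocity(e, falls[, "eta_P"])
  F_star <- peak_impact_force(m, u, constants)
  if (is.null(eta_ST)) eta_ST <- eta_st_from_bmi(compute_bmi(m, H))
  F <- attenuated_force(F_star, falls[, "eta_I"], eta_ST)
  list(e = e, u = u, F_star = F_star, F = F)
}

#' Per-fall fracture probability of a subject
#'
#' Monte Carlo / quadrature evaluation of the fracture-probability
#' integral: N Latin-hypercube falls of
#' `(theta_i, theta_f, v_i, a_i, eta_P, eta_I)` are drawn and chained
#' through the impact and force-transfer models (soft-tissue attenuation
#' fixed per subject from BMI); the fracture indicator is averaged over
#' falls at each of the surface's M orientations, and the averaged field
#' is integrated over `(alpha', beta')` with the uniform orientation
#' density. The same N falls are reused across all orientations, as the
#' separable structure of the integral implies.
#'
#' @param subj An [subject()] object, or a list with `m` and `H`.
#' @param surface The subject's [strength_surface()].
#' @param fall_model Named list of the six fall-parameter specs
#'   ([fall_model_default()]).
#' @param N Latin-hypercube sample size (>= 2); default 1e4, the verified
#'   setting.
#' @param seed Integer seed.
#' @param constants [fixed_constants()].
#' @return Fracture probability `P` in `[0, 1]`.
#' @export
fall_fracture_probability <- function(subj, surface,
                                      fall_model = fall_model_default(),
                                      N = 1e4, seed = 1L,
                                      constants = fixed_constants()) {
  stopifnot(inherits(surface, "arf_surface"))
  falls <- lh_sample(N, fall_model, seed)$matrix
  F <- fall_forces(subj$m, subj$H, falls, constants)$F
  # mean-over-falls of the indicator at each orientation, then quadrature
  chi_bar <- vapply(surface$values, function(s) mean(F >= s), numeric(1))
  integrate_field(chi_bar, surface$grid)
}

#' Annual absolute fracture risk from per-fall probability
#'
#' Probability of at least one fracture among `n_fall` mutually
#' independent falls in a year: `ARF0 = 100 * (1 - (1 - P)^n_fall)` (%).
#'
#' @param P Per-fall fracture probability in `[0, 1]`. Vectorised.
#' @param n_fall Annual fall rate (> 0).
#' @return ARF0 in percent.
#' @examples
#' arf0_from_p(0.03, 0.65)   # ~1.96%
#' @export
arf0_from_p <- function(P, n_fall = fixed_constants()$n_fall) {
  if (any(P < 0) || any(P > 1)) stop("P must lie in [0, 1]")
  if (n_fall <= 0) stop("fall rate must be strictly positive")
  100 * (1 - (1 - P)^n_fall)
}

#' Run the multiscale model over a cohort
#'
#' One risk prediction per subject, each from an independent seeded
#' substream. Subjects without a surface are reported as `NA` with a
#' warning; the run continues.
#'
#' @param subjects Data frame with columns `subject_id, mass_kg, height_m`
#'   (extra columns are carried along unmodified is not required).
#' @param surfaces Named list of [strength_surface()] objects keyed by
#'   `subject_id`.
#' @param fall_model Named list of six fall-parameter specs.
#' @param N Latin-hypercube sample size per subject (default 1e4).
#' @param seed Root seed; subject `i` uses substream `i`.
#' @param constants [fixed_constants()].
#' @return Data frame with columns
#'   `subject_id, P, ARF0_percent, N, M, seed`.
#' @export
run_cohort <- function(subjects, surfaces,
                       fall_model = fall_model_default(),
                       N = 1e4, seed = 1L,
                       constants = fixed_constants()) {
  need <- c("subject_id", "mass_kg", "height_m")
  if (!all(need %in% names(subjects))) {
    stop(sprintf("subjects must contain columns: %s",
                 paste(need, collapse = ", ")))
  }
  n <- nrow(subjects)
  P <- rep(NA_real_, n)
  M <- rep(NA_integer_, n)
  missing_ids <- character(0)
  for (i in seq_len(n)) {
    id <- as.character(subjects$subject_id[i])
    surf <- surfaces[[id]]
    if (is.null(surf)) {
      missing_ids <- c(missing_ids, id)
      next
    }
    P[i] <- fall_fracture_probability(
      list(m = subjects$mass_kg[i], H = subjects$height_m[i]),
      surf, fall_model, N = N, seed = .column_seed(seed, i),
      constants = constants)
    M[i] <- surf$grid$M
  }
  if (length(missing_ids) > 0) {
    warning(sprintf("no strength surface for subject(s): %s",
                    paste(missing_ids, collapse = ", ")))
  }
  ARF0 <- rep(NA_real_, n)
  ok <- !is.na(P)
  ARF0[ok] <- arf0_from_p(P[ok], constants$n_fall)
  data.frame(subject_id = as.character(subjects$subject_id),
             P = P, ARF0_percent = ARF0,
             N = as.integer(N), M = M, seed = as.integer(seed),
             stringsAsFactors = FALSE)
}
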