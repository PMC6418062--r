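#' Fixed model constants
#'
#' Constants shared by every stage of the multiscale fracture-risk model:
#' the centre-of-mass height ratio, the impact duration, the annual fall
#' rate, gravitational acceleration and the impact proportionality factor.
#'
#' @param c Ratio of standing centre-of-mass elevation to standing height
#'   (dimensionless). The pendulum length of the fall model is `c * H`.
#' @param dt Total impact duration in seconds; the peak force of the
#'   triangular impact pulse occurs at its midpoint.
#' @param n_fall Annual fall rate (falls/person/year), fixed across subjects.
#' @param g Gravitational acceleration (m s^-2). Configurable; 9.81 by
#'   default.
#' @param k Impact proportionality factor relating peak force to `2 m u / dt`.
#'   The default 0.5 absorbs into the simplified force expression `m u / dt`.
#'
#' @return An object of class `arf_constants` (a named list).
#' @examples
#' fixed_constants()
#' fixed_constants(n_fall = 1.0)
#' @export
fixed_constants <- function(c = 0.554, dt = 0.09, n_fall = 0.65,
                            g = 9.81, k = 0.5) {
  vals <- c(c = c, dt = dt, n_fall = n_fall, g = g, k = k)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all model constants must be finite and strictly positive")
  }
  if (c >= 1) stop("centre-of-mass height ratio 'c' must be < 1")
  structure(list(c = c, dt = dt, n_fall = n_fall, g = g, k = k),
            class = "arf_constants")
}

#' Truncated-normal parameter specification
#'
#' A stochastic fall parameter is described by a normal distribution
#' truncated symmetrically at +/- 3 SD. The truncation limits `(a, b)`
#' fully determine the distribution: the untruncated mean is `(a + b)/2`
#' and the untruncated SD is `(b - a)/6`.
#'
#' @param a Lower truncation limit (native units).
#' @param b Upper truncation limit (native units); must exceed `a`.
#' @return An object of class `arf_trunc_spec`.
#' @examples
#' trunc_spec(60, 120)   # final fall angle, degrees
#' @export
trunc_spec <- function(a, b) {
  if (!is.finite(a) || !is.finite(b)) stop("truncation limits must be finite")
  if (a >= b) stop("lower truncation limit 'a' must be strictly below 'b'")
  structure(list(a = a, b = b), class = "arf_trunc_spec")
}

#' Uniform parameter specification
#'
#' A uniform distribution on `[a, b]`, used for the sensitivity-analysis
#' input ranges.
#'
#' @inheritParams trunc_spec
#' @return An object of class `arf_unif_spec`.
#' @export
unif_spec <- function(a, b) {
  if (!is.finite(a) || !is.finite(b)) stop("range limits must be finite")
  if (a >= b) stop("lower limit 'a' must be strictly below 'b'")
  structure(list(a = a, b = b), class = "arf_unif_spec")
}

#' Default stochastic fall model
#'
#' The six fall-stochasticity parameters with their default truncation
#' values: initial and final pendulum angle (degrees), initial linear
#' velocity and acceleration of the centre of mass (`cH * dtheta/dt`,
#' `cH * d2theta/dt2`; m s^-1 and m s^-2, so that the distributions are
#' subject-independent), the postural reflex attenuation `eta_P`, and the
#' combined impact attenuation `eta_I` (whose lower bound is negative:
#' active muscle contraction can amplify the transmitted force).
#'
#' @return A named list of [trunc_spec()] objects with class
#'   `arf_fall_model`, in the canonical order
#'   `theta_i, theta_f, v_i, a_i, eta_P, eta_I`.
#' @examples
#' fall_model_default()$eta_I
#' @export
fall_model_default <- function() {
  structure(list(
    theta_i = trunc_spec(0, 30),
    theta_f = trunc_spec(60, 120),
    v_i     = trunc_spec(0, 1.40),
    a_i     = trunc_spec(0, 5.10),
    eta_P   = trunc_spec(0.500, 0.800),
    eta_I   = trunc_spec(-2.55, 0.914)
  ), class = "arf_fall_model")
}

#' Construct a subject
#'
#' @param subject_id Character identifier.
#' @param m Body mass in kg (> 0).
#' @param H Standing height in m (> 0).
#' @param age Age in years (optional).
#' @param group Optional group tag (`"fracture"` / `"non-fracture"`).
#' @param fracture_label Optional binary fracture label (0/1).
#' @return A list of class `arf_subject` with a derived `bmi` field.
#' @export
subject <- function(subject_id, m, H, age = NA_real_, group = NA_character_,
                    fracture_label = NA_integer_) {
  bmi <- compute_bmi(m, H)
  structure(list(subject_id = as.character(subject_id), m = m, H = H,
                 age = age, group = group,
                 fracture_label = fracture_label, bmi = bmi),
            class = "arf_subject")
}

#' Body mass index
#'
#' @param m Body mass in kg (> 0).
#' @param H Standing height in m (> 0). Vectorised.
#' @return BMI in kg m^-2, `m / H^2`.
#' @examples
#' compute_bmi(62.6, 1.58)
#' @export
compute_bmi <- function(m, H) {
  if (any(!is.finite(m)) || any(!is.finite(H)) || any(m <= 0) || any(H <= 0)) {
    stop("mass and height must be finite and strictly positive")
  }
  m / H^2
}

# Fraction of normal probability mass within +/- 3 SD, and the variance
# deflation of the +/- 3 SD truncated normal: var_trunc/var = 1 - 6*phi(3)/Z.
.z3 <- stats::pnorm(3) - stats::pnorm(-3)
.trunc_var_ratio <- 1 - 6 * stats::dnorm(3) / .z3

#' Moments of a +/- 3 SD truncated normal
#'
#' Returns the untruncated mean/SD implied by the truncation limits and
#' the exact mean and variance of the truncated distribution. By symmetry
#' the truncated mean equals the untruncated mean; the truncated variance
#' is deflated by the closed-form factor
#' `1 - 6 phi(3) / (Phi(3) - Phi(-3))` (about 0.97334), identical for
#' every spec (scale invariance).
#'
#' @param spec A [trunc_spec()].
#' @return A list with `mu`, `sigma` (untruncated), `mu_trunc`, `var_trunc`.
#' @examples
#' truncated_moments(trunc_spec(60, 120))
#' @export
truncated_moments <- function(spec) {
  stopifnot(inherits(spec, "arf_trunc_spec"))
  mu <- (spec$a + spec$b) / 2
  sigma <- (spec$b - spec$a) / 6
  list(mu = mu, sigma = sigma,
       mu_trunc = mu,
       var_trunc = sigma^2 * .trunc_var_ratio)
}

#' @export
print.arf_constants <- function(x, ...) {
  cat("Fixed model constants:\n")
  cat(sprintf("  c = %g, dt = %g s, n_fall = %g /yr, g = %g m/s^2, k = %g\n",
              x$c, x$dt, x$n_fall, x$g, x$k))
  invisible(x)
}

#' @export
print.arf_trunc_spec <- function(x, ...) {
  mom <- truncated_moments(x)
  cat(sprintf(
    "Truncated normal on [%g, %g] (mu = %g, sigma = %g, +/-3 SD)\n",
    x$a, x$b, mom$mu, mom$sigma))
  invisible(x)
}
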