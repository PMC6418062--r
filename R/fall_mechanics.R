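#' Kinetic energy per unit mass at the end of a fall
#'
#' Inverted-pendulum energy balance: a body of height `H` with its centre
#' of mass at elevation `cH` rotates from `theta_i` to `theta_f` (angles
#' from the vertical, in degrees), starting with linear centre-of-mass
#' velocity `v_i = cH * dtheta_i/dt` and acceleration
#' `a_i = cH * d2theta_i/dt2`. The available specific kinetic energy is
#'
#'   `e = cH * a_i * (theta_f - theta_i) + v_i^2 / 2
#'        + g * cH * (cos theta_i - cos theta_f)`
#'
#' with the angle difference in radians. The first term is computed as
#' `cH * (cH * d2theta/dt2) * dtheta` so the linear acceleration bound can
#' be used directly; algebraically identical to `c^2 H^2 d2theta/dt2 dtheta`.
#'
#' @param H Standing height (m). Vectorised with the fall parameters.
#' @param theta_i,theta_f Initial/final pendulum angle from vertical (deg);
#'   `theta_f > theta_i` required.
#' @param v_i Initial linear COM velocity `cH * dtheta_i/dt` (m s^-1).
#' @param a_i Initial linear COM acceleration `cH * d2theta_i/dt2` (m s^-2).
#' @param constants [fixed_constants()].
#' @return Specific kinetic energy `e` (J kg^-1), clamped at 0 (with a
#'   warning) for pathological parameter combinations; cannot occur inside
#'   the default parameter ranges where the gravity term dominates.
#' @examples
#' kinetic_energy(1.58, 0, 90, 0, 0)   # pure gravitational drop: g*c*H
#' @export
kinetic_energy <- function(H, theta_i, theta_f, v_i, a_i,
                           constants = fixed_constants()) {
  if (any(H <= 0)) stop("height must be strictly positive")
  if (any(theta_f <= theta_i)) {
    stop("the fall must progress: theta_f must exceed theta_i")
  }
  ch <- constants$c * H
  dth <- (theta_f - theta_i) * pi / 180
  e <- ch * a_i * dth + 0.5 * v_i^2 +
    constants$g * ch * (cos(theta_i * pi / 180) - cos(theta_f * pi / 180))
  if (any(e < 0)) {
    warning(sprintf("%d fall(s) produced negative kinetic energy; clamped to 0",
                    sum(e < 0)))
    e <- pmax(e, 0)
  }
  e
}

#' Hip impact velocity
#'
#' `u = sqrt(2 * (1 - eta_P) * e)`: the postural reflex attenuation
#' coefficient `eta_P` removes a fraction of the fall's kinetic energy
#' (protective responses, partial interruption) before impact.
#'
#' @param e Specific kinetic energy (J kg^-1, >= 0).
#' @param eta_P Postural reflex attenuation in `[0, 1]`.
#' @return Impact velocity `u` (m s^-1).
#' @export
impact_velocity <- function(e, eta_P) {
  if (any(e < 0)) stop("kinetic energy must be non-negative")
  if (any(eta_P < 0) || any(eta_P > 1)) {
    stop("postural attenuation eta_P must lie in [0, 1]")
  }
  sqrt(2 * (1 - eta_P) * e)
}

#' Unattenuated peak impact force
#'
#' The impact force pulse is triangular in time with total duration `dt`,
#' so the peak force is `F* = k * 2 m u / dt`; experimental calibration
#' puts the proportionality factor `k` at 0.5, giving the simplified
#' `F* = m u / dt` used throughout.
#'
#' @param m Body mass (kg, > 0).
#' @param u Hip impact velocity (m s^-1, >= 0).
#' @param constants [fixed_constants()]; `k` and `dt` are used.
#' @return Peak impact force `F*` (N).
#' @examples
#' peak_impact_force(61.2, 3)   # the calibration case, ~2040 N
#' @export
peak_impact_force <- function(m, u, constants = fixed_constants()) {
  if (any(m <= 0)) stop("mass must be strictly positive")
  if (any(u < 0)) stop("impact velocity must be non-negative")
  constants$k * 2 * m * u / constants$dt
}
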