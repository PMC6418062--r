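#' Orientation grids over the side-fall loading domain
#'
#' Femoral strength is evaluated at M nominally uniformly spaced impact
#' orientations `(alpha', beta')` covering `[-30, +30] x [0, +30]` degrees
#' (rotations of the impact force about the femoral z and x axes). The
#' supported counts are rectangular lattices whose refinements nest the
#' domain: 4 = 2x2 (corners), 15 = 5x3, 33 = 11x3, 66 = 11x6, 231 = 21x11.
#' Each lattice cell is split into two triangles along the diagonal from
#' its lower-left to its upper-right corner, giving a deterministic
#' triangulation covering the rectangle exactly.
#'
#' @param M Number of orientation points; one of 4, 15, 33, 66, 231.
#' @return An object of class `arf_grid`: list with `points` (M x 2 matrix,
#'   columns `alpha_deg`, `beta_deg`), `triangles` (T x 3 vertex indices),
#'   `weights` (vertex quadrature weights summing to 1) and `M`.
#' @examples
#' g <- build_orientation_grid(33)
#' range(g$points[, "alpha_deg"])
#' @export
build_orientation_grid <- function(M) {
  layouts <- list(`4` = c(2, 2), `15` = c(5, 3), `33` = c(11, 3),
                  `66` = c(11, 6), `231` = c(21, 11))
  key <- as.character(M)
  if (!key %in% names(layouts)) {
    stop("unsupported orientation count M; use one of 4, 15, 33, 66, 231")
  }
  na <- layouts[[key]][1]
  nb <- layouts[[key]][2]
  alpha <- seq(-30, 30, length.out = na)
  beta <- seq(0, 30, length.out = nb)
  pts <- as.matrix(expand.grid(alpha_deg = alpha, beta_deg = beta,
                               KEEP.OUT.ATTRS = FALSE))
  # triangles: cell (i, j) -> indices into pts (alpha varies fastest)
  tri <- matrix(NA_integer_, nrow = 2 * (na - 1) * (nb - 1), ncol = 3)
  t_idx <- 0L
  for (j in seq_len(nb - 1)) {
    for (i in seq_len(na - 1)) {
      ll <- (j - 1) * na + i
      lr <- ll + 1L
      ul <- ll + na
      ur <- ul + 1L
      tri[t_idx + 1L, ] <- c(ll, lr, ur)
      tri[t_idx + 2L, ] <- c(ll, ur, ul)
      t_idx <- t_idx + 2L
    }
  }
  # linear-interpolant quadrature: each triangle contributes area/3 per
  # vertex; normalising by the domain area (1800 deg^2) gives weights
  cell_area <- (alpha[2] - alpha[1]) * (beta[2] - beta[1])
  tri_area <- cell_area / 2
  w <- numeric(nrow(pts))
  for (t in seq_len(nrow(tri))) {
    w[tri[t, ]] <- w[tri[t, ]] + tri_area / 3
  }
  w <- w / sum(w)
  structure(list(points = pts, triangles = tri, weights = w, M = nrow(pts)),
            class = "arf_grid")
}

#' Integrate a field over the orientation domain
#'
#' Integral of the piecewise-linear interpolant of per-orientation values
#' against the uniform orientation density: every triangle contributes its
#' area times the mean of its vertex values, normalised by the total
#' domain area. Exact for fields linear in `(alpha', beta')`; reduces to
#' the precomputed vertex-weight inner product.
#'
#' @param field Numeric vector of length `grid$M`.
#' @param grid An [build_orientation_grid()] object.
#' @return Scalar; equals the field value for constant fields.
#' @export
integrate_field <- function(field, grid) {
  stopifnot(inherits(grid, "arf_grid"))
  if (length(field) != grid$M) {
    stop(sprintf("field length %d does not match grid size M = %d",
                 length(field), grid$M))
  }
  sum(grid$weights * field)
}

#' Construct a femoral strength surface
#'
#' @param subject_id Character identifier.
#' @param grid An [build_orientation_grid()] object.
#' @param values Strength (N) at each grid orientation; all > 0.
#' @return An object of class `arf_surface`.
#' @export
strength_surface <- function(subject_id, grid, values) {
  stopifnot(inherits(grid, "arf_grid"))
  if (length(values) != grid$M) stop("values length must equal grid size M")
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("strength values must be finite and strictly positive")
  }
  structure(list(subject_id = as.character(subject_id), grid = grid,
                 values = as.numeric(values)),
            class = "arf_surface")
}

#' Summary statistics of a strength surface
#'
#' @param surface An [strength_surface()] object.
#' @return List with `S_min`, `S_max`, `S_mean` (arithmetic mean over the
#'   M orientations, the `<S>` used for subject-level correlations).
#' @export
surface_stats <- function(surface) {
  stopifnot(inherits(surface, "arf_surface"))
  list(S_min = min(surface$values), S_max = max(surface$values),
       S_mean = mean(surface$values))
}

# Normalised shape coordinates on the orientation domain
.shape_xy <- function(alpha_deg, beta_deg) {
  list(x = alpha_deg / 30, y = beta_deg / 30 - 0.5)
}

#' Population-mean anisotropy shape of the surrogate strength model
#'
#' Smooth positive field of unit arithmetic grid mean describing how
#' side-fall strength varies with impact orientation in the population:
#' mildly higher for more adducted/internally rotated impacts and reduced
#' towards extreme abduction angles. Evaluable at arbitrary orientations,
#' so grid refinement of synthetic surfaces is exact.
#'
#' @param alpha_deg,beta_deg Orientation coordinates in degrees (vectors).
#' @return Shape values (unnormalised; see [synthesize_surface()]).
#' @export
base_shape_field <- function(alpha_deg, beta_deg) {
  s <- .shape_xy(alpha_deg, beta_deg)
  1 + 0.20 * s$y - 0.15 * s$x^2 + 0.08 * s$x * s$y
}

# low-order polynomial basis for per-subject shape perturbations
.shape_basis <- function(alpha_deg, beta_deg) {
  s <- .shape_xy(alpha_deg, beta_deg)
  cbind(b1 = s$x, b2 = s$y, b3 = s$x * s$y, b4 = s$x^2, b5 = s$y^2)
}

#' Synthesise a subject-specific strength surface
#'
#' Surrogate for CT-based finite-element strength estimation: the surface
#' is `S(alpha', beta') = S_mean * f(alpha', beta')` where `f` is the
#' population-mean anisotropy shape perturbed by a low-order polynomial in
#' the normalised orientation coordinates with per-subject coefficients,
#' renormalised to unit arithmetic mean over the grid so that the mean
#' strength over orientations equals `S_mean` exactly.
#'
#' @param subject_id Character identifier.
#' @param S_mean Subject's orientation-averaged strength (N, > 0).
#' @param grid An [build_orientation_grid()] object.
#' @param shape_coefs Numeric vector of 5 per-subject shape coefficients
#'   (typically +/- 3-truncated standard normal draws).
#' @param amp Shape-perturbation amplitude (default 0.08), chosen so the
#'   bulk of subjects remain at least moderately correlated (r >= 0.5)
#'   with the population-mean surface.
#' @return An [strength_surface()] object.
#' @export
synthesize_surface <- function(subject_id, S_mean, grid, shape_coefs,
                               amp = 0.08) {
  stopifnot(inherits(grid, "arf_grid"))
  if (length(shape_coefs) != 5) stop("shape_coefs must have length 5")
  if (S_mean <= 0) stop("mean strength must be strictly positive")
  a <- grid$points[, "alpha_deg"]
  b <- grid$points[, "beta_deg"]
  f <- base_shape_field(a, b) +
    amp * as.numeric(.shape_basis(a, b) %*% shape_coefs)
  f <- f / mean(f)
  if (any(f <= 0)) {
    stop("shape parameters produced non-positive strengths; reduce 'amp'")
  }
  strength_surface(subject_id, grid, S_mean * f)
}

#' Write strength surfaces to a long-format CSV
#'
#' Columns `subject_id, alpha_deg, beta_deg, strength_N`; one row per
#' subject-orientation.
#'
#' @param surfaces A list of [strength_surface()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_strength_csv <- function(surfaces, path) {
  rows <- lapply(surfaces, function(s) {
    data.frame(subject_id = s$subject_id,
               alpha_deg = s$grid$points[, "alpha_deg"],
               beta_deg = s$grid$points[, "beta_deg"],
               strength_N = s$values)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(subject_id = character(), alpha_deg = numeric(),
                     beta_deg = numeric(), strength_N = numeric())
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read strength surfaces from a long-format CSV
#'
#' Validates that every subject carries a complete supported orientation
#' grid (same M for all subjects, all lattice points present exactly once).
#'
#' @param path CSV with columns `subject_id, alpha_deg, beta_deg, strength_N`.
#' @return Named list of [strength_surface()] objects.
#' @export
read_strength_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "alpha_deg", "beta_deg", "strength_N")
  if (!all(need %in% names(df))) {
    stop(sprintf("strength CSV %s must contain columns: %s",
                 path, paste(need, collapse = ", ")))
  }
  if (nrow(df) == 0) return(structure(list(), names = character()))
  ids <- unique(df$subject_id)
  # the grid size is the modal per-subject row count, so a subject with a
  # missing orientation is diagnosed as incomplete rather than corrupting
  # the inferred layout
  counts <- table(df$subject_id)
  M <- as.integer(max(counts))
  grid <- build_orientation_grid(M)
  key <- paste(round(grid$points[, "alpha_deg"], 6),
               round(grid$points[, "beta_deg"], 6))
  out <- lapply(ids, function(id) {
    sub <- df[df$subject_id == id, ]
    k <- paste(round(sub$alpha_deg, 6), round(sub$beta_deg, 6))
    miss <- setdiff(key, k)
    if (nrow(sub) != M || length(miss) > 0) {
      stop(sprintf("subject %s: incomplete strength grid (missing orientation %s)",
                   id, if (length(miss)) miss[1] else "rows"))
    }
    strength_surface(id, grid, sub$strength_N[match(key, k)])
  })
  names(out) <- ids
  out
}
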