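#' Quantile function of a +/- 3 SD truncated normal
#'
#' Inverse CDF of the truncated distribution described by `spec`:
#' `mu + sigma * qnorm(pnorm(-3) + q * (pnorm(3) - pnorm(-3)))`.
#'
#' @param q Probabilities in (0, 1); vectorised.
#' @param spec A [trunc_spec()].
#' @return Values in `[a, b]` on the native scale.
#' @examples
#' truncnorm_ppf(0.5, trunc_spec(60, 120))  # 90, the symmetric median
#' @export
truncnorm_ppf <- function(q, spec) {
  stopifnot(inherits(spec, "arf_trunc_spec"))
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1)) {
    stop("probabilities must lie strictly inside (0, 1)")
  }
  mom <- truncated_moments(spec)
  p_lo <- stats::pnorm(-3)
  mom$mu + mom$sigma * stats::qnorm(p_lo + q * .z3)
}

# quantile dispatch shared by lh_sample(): truncated-normal or uniform columns
.spec_ppf <- function(q, spec) {
  if (inherits(spec, "arf_trunc_spec")) {
    truncnorm_ppf(q, spec)
  } else if (inherits(spec, "arf_unif_spec")) {
    spec$a + (spec$b - spec$a) * q
  } else {
    stop("spec must be a trunc_spec or unif_spec")
  }
}

# Independent per-column substream seeds derived from one root seed, so
# adding or removing a column never reshuffles the draws of another.
.column_seed <- function(seed, j) {
  as.integer((as.double(seed) + 7919 * j) %% 2147483629)
}

#' Inverse-transformed Latin-hypercube sample
#'
#' Draws `n` stratified samples per parameter: each column places exactly
#' one draw in every probability stratum of width `1/n` (uniform jitter
#' within the stratum), permutes the strata independently of other
#' columns, and maps the stratified uniforms through the parameter's
#' quantile function. Reproducible for a fixed seed; each column uses its
#' own substream derived from the root seed.
#'
#' @param n Sample size (>= 2).
#' @param specs Named list of [trunc_spec()] / [unif_spec()] objects.
#' @param seed Integer root seed.
#' @return An object of class `arf_lh_sample`: list with `matrix`
#'   (`n` x `d`, columns named after `specs`), `seed` and `specs`.
#' @examples
#' s <- lh_sample(100, fall_model_default(), seed = 1)
#' colMeans(s$matrix)
#' @export
lh_sample <- function(n, specs, seed) {
  if (n < 2) stop("Latin-hypercube sample size must be at least 2")
  if (is.null(names(specs)) || any(names(specs) == "")) {
    stop("'specs' must be a fully named list")
  }
  d <- length(specs)
  mat <- matrix(NA_real_, nrow = n, ncol = d,
                dimnames = list(NULL, names(specs)))
  for (j in seq_len(d)) {
    rng <- .substream(.column_seed(seed, j))
    perm <- rng$sample(n)
    u <- (perm - rng$runif(n)) / n
    mat[, j] <- .spec_ppf(u, specs[[j]])
  }
  structure(list(matrix = mat, seed = as.integer(seed), specs = specs),
            class = "arf_lh_sample")
}

# Small RNG-substream helper: isolates set.seed() so callers' RNG state
# is untouched.
.substream <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    st
  })
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- expr()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(
    sample = function(n) with_state(function() sample.int(n)),
    runif  = function(n) with_state(function() stats::runif(n)),
    rnorm  = function(n) with_state(function() stats::rnorm(n))
  )
}

#' Iman-Conover rank-correlation induction
#'
#' Rearranges the rows within each column of a sample so that the Spearman
#' rank correlations approach a target matrix while each column's marginal
#' multiset is left exactly unchanged. Classic van der Waerden score
#' implementation: a score matrix with the target correlation structure is
#' built via Cholesky adjustment, and every data column is reordered to
#' match the ranks of the corresponding score column.
#'
#' @param sample An `arf_lh_sample` or a numeric matrix.
#' @param target Symmetric positive-definite target rank-correlation matrix
#'   with unit diagonal (`d` x `d`).
#' @param seed Integer seed for the random score permutations.
#' @return Same type as `sample`, with reordered columns.
#' @export
iman_conover <- function(sample, target, seed = 1L) {
  is_lh <- inherits(sample, "arf_lh_sample")
  x <- if (is_lh) sample$matrix else as.matrix(sample)
  n <- nrow(x); d <- ncol(x)
  if (!isTRUE(all.equal(dim(target), c(d, d))) ||
      !isTRUE(all.equal(target, t(target))) ||
      !isTRUE(all.equal(diag(target), rep(1, d), check.attributes = FALSE))) {
    stop("target must be a symmetric matrix with unit diagonal matching the sample dimension")
  }
  # the scores are Gaussian, so hitting a Spearman target requires the
  # classical Pearson conversion 2 sin(pi r / 6) on the score correlation
  target_score <- 2 * sin(pi * target / 6)
  diag(target_score) <- 1
  P <- tryCatch(chol(target_score),
                error = function(e) stop("target rank-correlation matrix is not positive definite"))
  scores <- stats::qnorm(seq_len(n) / (n + 1))   # van der Waerden scores
  M <- matrix(NA_real_, n, d)
  for (j in seq_len(d)) {
    rng <- .substream(.column_seed(seed, j + 104729L))
    M[, j] <- scores[rng$sample(n)]
  }
  E <- stats::cor(M)
  # for very small n the random score matrix can be singular; the
  # decorrelation step is then skipped (E is close to the identity anyway)
  Fc <- tryCatch(chol(E), error = function(e) diag(d))
  Tm <- M %*% solve(Fc) %*% P   # cor(Tm) ~ target
  out <- x
  for (j in seq_len(d)) {
    out[, j] <- sort(x[, j])[rank(Tm[, j], ties.method = "first")]
  }
  if (is_lh) {
    sample$matrix <- out
    sample
  } else {
    out
  }
}
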