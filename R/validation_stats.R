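#' Mann-Whitney group comparison
#'
#' Rank-sum comparison of a score (here ARF0) between two groups. Exact
#' permutation p-value for small untied samples, normal approximation
#' with tie correction otherwise (delegated to [stats::wilcox.test()],
#' which implements exactly this policy).
#'
#' @param group_a,group_b Numeric score vectors; both non-empty.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (of `group_a` relative to `group_b`).
#' @return List with `U` (the Mann-Whitney statistic of `group_a`) and
#'   `p`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6), alternative = "less")  # p = 0.05
#' @export
mann_whitney <- function(group_a, group_b, alternative = "two.sided") {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty")
  }
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = alternative,
                       exact = NULL, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

# Wilson score confidence interval for a binomial proportion
.wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' ROC analysis with Youden-optimal threshold
#'
#' Empirical ROC curve of a risk score against binary labels: AUC by the
#' trapezoidal rule, AUC confidence interval by seeded stratified
#' bootstrap, operating point by the Youden index (`sens + spec - 1`)
#' evaluated at midpoints between consecutive observed scores (ties
#' broken towards higher specificity), and Wilson score intervals for
#' sensitivity and specificity at that threshold. ROC/AUC computation is
#' delegated to \pkg{pROC}.
#'
#' @param scores Numeric risk scores (e.g. ARF0 in percent); higher
#'   scores must indicate cases.
#' @param labels Binary labels (0 = control, 1 = case); both classes
#'   must be present.
#' @param boot Bootstrap replicates for the AUC interval (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return List of class `arf_roc` with `auc`, `auc_ci`, `threshold`,
#'   `sensitivity`, `sensitivity_ci`, `specificity`, `specificity_ci`,
#'   and `curve` (data frame `threshold, sensitivity, specificity`).
#' @export
roc_analysis <- function(scores, labels, boot = 2000, conf = 0.95,
                         seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present in the labels")
  }
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  set.seed(seed)
  ci <- suppressWarnings(
    pROC::ci.auc(r, conf.level = conf, method = "bootstrap",
                 boot.n = boot, boot.stratified = TRUE, progress = "none"))
  co <- pROC::coords(r, x = "best", best.method = "youden",
                     ret = c("threshold", "sensitivity", "specificity"),
                     transpose = FALSE)
  if (nrow(co) > 1) co <- co[which.max(co$specificity), , drop = FALSE]
  n_case <- sum(labels == 1)
  n_ctrl <- sum(labels == 0)
  sens <- co$sensitivity
  spec <- co$specificity
  all_co <- pROC::coords(r, ret = c("threshold", "sensitivity",
                                    "specificity"), transpose = FALSE)
  structure(list(
    auc = auc,
    auc_ci = c(lower = unname(ci[1]), upper = unname(ci[3])),
    threshold = co$threshold,
    sensitivity = sens,
    sensitivity_ci = .wilson_ci(round(sens * n_case), n_case, conf),
    specificity = spec,
    specificity_ci = .wilson_ci(round(spec * n_ctrl), n_ctrl, conf),
    curve = all_co
  ), class = "arf_roc")
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Decile-of-risk calibration test for fitted event probabilities:
#' observations are grouped by probability quantiles, degenerate
#' (identical-boundary) groups are merged with a warning, and the
#' statistic `sum((O - E)^2 / (E (1 - E/n)))` over groups is referred to
#' a chi-squared distribution with `g - 2` degrees of freedom.
#'
#' @param probabilities Fitted event probabilities (from a logistic
#'   model of label on the risk score).
#' @param labels Binary outcomes (0/1).
#' @param g Number of groups (default 10); must not exceed `n`.
#' @return List with `chi2`, `df`, `p`, `g_used`.
#' @export
hosmer_lemeshow <- function(probabilities, labels, g = 10) {
  n <- length(probabilities)
  labels <- as.integer(labels)
  if (g > n) stop("more groups than observations")
  if (g < 2) stop("at least 2 groups are required")
  br <- unique(stats::quantile(probabilities, probs = seq(0, 1, length.out = g + 1)))
  if (length(br) < g + 1) {
    warning("degenerate probability groups merged")
  }
  grp <- if (length(br) < 3) {
    factor(rep(1L, n))   # all probabilities (near-)identical: one group
  } else {
    cut(probabilities, breaks = br, include.lowest = TRUE)
  }
  obs <- tapply(labels, grp, sum)
  exp_ <- tapply(probabilities, grp, sum)
  cnt <- tapply(labels, grp, length)
  keep <- !is.na(obs) & cnt > 0
  obs <- obs[keep]; exp_ <- exp_[keep]; cnt <- cnt[keep]
  g_used <- length(obs)
  chi2 <- sum((obs - exp_)^2 / pmax(exp_ * (1 - exp_ / cnt), .Machine$double.eps))
  df <- max(1, g_used - 2)
  list(chi2 = unname(chi2), df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE), g_used = g_used)
}

#' Full validation report for a scored cohort
#'
#' Convenience wrapper chaining the three validation statistics: the
#' Mann-Whitney comparison of ARF0 between fracture and non-fracture
#' subjects, a univariate logistic fit of label on ARF0 followed by the
#' Hosmer-Lemeshow calibration test, and the ROC/Youden classification
#' analysis.
#'
#' @param arf0 ARF0 scores in percent.
#' @param labels Binary fracture labels.
#' @param seed Seed for the bootstrap interval.
#' @return List with `mw` ([mann_whitney()]), `hl`
#'   ([hosmer_lemeshow()]), `roc` ([roc_analysis()]), and the fitted
#'   logistic `model`.
#' @export
validate_cohort <- function(arf0, labels, seed = 1L) {
  labels <- as.integer(labels)
  mw <- mann_whitney(arf0[labels == 1], arf0[labels == 0])
  fit <- stats::glm(labels ~ arf0, family = stats::binomial())
  hl <- hosmer_lemeshow(stats::fitted(fit), labels)
  roc <- roc_analysis(arf0, labels, seed = seed)
  list(mw = mw, hl = hl, roc = roc, model = fit)
}

#' @export
print.arf_roc <- function(x, ...) {
  cat(sprintf("AUC = %.3f (%.0f%% CI %.3f-%.3f)\n", x$auc, 95,
              x$auc_ci["lower"], x$auc_ci["upper"]))
  cat(sprintf("Youden threshold = %.3g: sens %.3f, spec %.3f\n",
              x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}
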