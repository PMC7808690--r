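# Cohort-level statistics: ordinary least-squares age regressions with
# confidence intervals, two-sided Mann-Whitney group comparisons with
# Bonferroni correction, and per-sample correlations between mutation
# classes.

#' Linear regression of a per-sample quantity on donor age
#'
#' Ordinary least squares of `values` on `ages`; the slope confidence
#' interval comes from the t distribution.
#'
#' @param values numeric per-sample values
#' @param ages donor ages in years, paired with `values`
#' @param conf_level confidence level (default 0.95)
#' @return object of class `cohort_fit`: slope (units per year), intercept,
#'   slope CI, slope p-value, n, and the underlying `lm` fit
#' @export
regress_vs_age <- function(values, ages, conf_level = 0.95) {
  check_that(length(values) == length(ages), "values and ages differ in length")
  ok <- !is.na(values) & !is.na(ages)
  values <- values[ok]; ages <- ages[ok]
  check_that(length(values) >= 3, "need at least 3 paired observations")
  check_that(length(unique(ages)) > 1, "ages are constant")
  fit <- stats::lm(values ~ ages)
  sm <- summary(fit)
  ci <- stats::confint(fit, "ages", level = conf_level)
  structure(list(
    slope = unname(coef(fit)["ages"]),
    intercept = unname(coef(fit)["(Intercept)"]),
    ci = c(lower = ci[1], upper = ci[2]),
    p = sm$coefficients["ages", "Pr(>|t|)"],
    n = length(values),
    conf_level = conf_level,
    fit = fit,
    xlab = "age"), class = "cohort_fit")
}

#' Regression of one per-sample quantity on another
#'
#' OLS of `y` on `x` with slope CI and p-value; used for e.g. deletions
#' >= 5 bp against the UV minimum mutation load.
#'
#' @param x,y paired per-sample values
#' @param conf_level confidence level (default 0.95)
#' @return `cohort_fit` object
#' @export
correlate <- function(x, y, conf_level = 0.95) {
  out <- regress_vs_age(y, x, conf_level)
  out$xlab <- "x"
  out
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): slope = %.4g per %s (%.0f%% CI %.4g to %.4g), p = %.3g\n",
              x$n, x$slope, x$xlab, 100 * x$conf_level, x$ci["lower"],
              x$ci["upper"], x$p))
  invisible(x)
}

#' Two-group Mann-Whitney comparison
#'
#' Two-sided Mann-Whitney U test (exact when the combined sample is small
#' and tie-free, normal approximation with tie correction otherwise, as in
#' [stats::wilcox.test()]), with per-group medians and a Bonferroni-corrected
#' p-value for a family of `family_size` endpoints.
#'
#' @param values numeric values
#' @param labels two-level grouping vector paired with `values`
#' @param family_size number of comparisons in the Bonferroni family
#'   (default 1 = no correction)
#' @param exclude optional logical; TRUE entries are dropped first (e.g. the
#'   melanocyte-exclusion sensitivity analysis)
#' @return object of class `group_comparison`
#' @export
compare_groups <- function(values, labels, family_size = 1, exclude = NULL) {
  check_that(length(values) == length(labels), "values and labels differ in length")
  if (!is.null(exclude)) {
    values <- values[!exclude]; labels <- labels[!exclude]
  }
  labels <- as.character(labels)
  lv <- unique(labels)
  check_that(length(lv) == 2, "need exactly two groups")
  a <- values[labels == lv[1]]
  b <- values[labels == lv[2]]
  check_that(length(a) >= 1 && length(b) >= 1, "a group is empty")
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  structure(list(
    groups = lv,
    n = c(length(a), length(b)),
    medians = c(median(a), median(b)),
    U = unname(wt$statistic),
    p = wt$p.value,
    p_bonferroni = min(1, wt$p.value * family_size),
    family_size = family_size), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney: %s (n=%d, median %.4g) vs %s (n=%d, median %.4g)\n",
              x$groups[1], x$n[1], x$medians[1], x$groups[2], x$n[2],
              x$medians[2]))
  cat(sprintf("  U = %g, two-sided p = %.4g (Bonferroni x%d: %.4g)\n",
              x$U, x$p, x$family_size, x$p_bonferroni))
  invisible(x)
}
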