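#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' The standard arm-versus-arm comparison used for ablation-area, hemoglobin
#' and FDP outcomes: a one-way ANOVA F test across groups followed by Tukey
#' honest-significant-difference adjusted pairwise decisions.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor), same length as `values`.
#' @param alpha Significance level for the pairwise decisions (default 0.05).
#' @return A list of class `anova_tukey` with the ANOVA `F`, its `p_value`,
#'   and a data frame `pairs` (pair, difference, adjusted p, significant).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least two samples")
  fit <- aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$groups
  pairs <- data.frame(pair = rownames(tk), difference = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL)
  structure(list(F = an$`F value`[1], p_value = an$`Pr(>F)`[1],
                 alpha = alpha, pairs = pairs),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3g, p = %.3g\n", x$F, x$p_value))
  print(x$pairs, digits = 3)
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y Paired numeric samples (length >= 3, non-degenerate).
#' @return List with `r` (correlation) and `p_value` (two-sided test).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("'x' and 'y' must be paired samples of length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for zero-variance samples")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Z-score linear regression coefficient
#'
#' Least-squares slope of z-scored fibrin-degradation-product totals against
#' z-scored hemoglobin over a pressure sweep; numerically equal to the
#' Pearson correlation of the raw pairs.  A coefficient near one means
#' hemolysis and fibrinolysis increase in proportion; values near zero (or an
#' undefined coefficient, returned as `NA` when hemoglobin does not vary, as
#' happens for nearly pure-fibrin sections) mean histotripsy drives only one
#' of the two.
#'
#' @param hemoglobin Hemoglobin totals across the pressure sweep (ng).
#' @param fdp FDP totals across the same sweep.
#' @return Dimensionless slope, or `NA` if either variable has zero variance.
#' @export
linear_regression_coefficient <- function(hemoglobin, fdp) {
  if (length(hemoglobin) != length(fdp) || length(hemoglobin) < 3)
    stop("need paired sweeps of length >= 3")
  if (sd(hemoglobin) == 0 || sd(fdp) == 0) return(NA_real_)
  zx <- (hemoglobin - mean(hemoglobin)) / sd(hemoglobin)
  zy <- (fdp - mean(fdp)) / sd(fdp)
  unname(coef(stats::lm(zy ~ zx))[2])
}
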