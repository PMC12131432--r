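# The validation analysis plan: normality-routed two-group comparisons,
# contingency and McNemar tests, correlation, collinearity-screened
# multilinear regression, ROC classification accuracy and the assembled
# cohort report.

#' Two-group comparison with normality routing
#'
#' Runs a Shapiro-Wilk test on both samples; when neither rejects at
#' `alpha_normality` the groups are compared with a two-tailed Student's
#' t-test, otherwise with a two-tailed Mann-Whitney U test. The routing
#' decision and both normality p-values are recorded in the result.
#'
#' @param x,y Numeric samples (each n >= 3).
#' @param alpha_normality Rejection level for the Shapiro-Wilk tests.
#' @param var_equal Use the classical equal-variance t statistic (default)
#'   rather than the Welch correction.
#' @return An object of class `group_comparison`: list with `test_name`
#'   (`"t"` or `"MannWhitney"`), `statistic`, `p_value`, group `means` and
#'   `sds`, `shapiro_p` and `routing_reason`.
#' @export
compare_groups <- function(x, y, alpha_normality = 0.05, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L) {
    artix_error("artix_bad_input", "each sample needs at least 3 observations")
  }
  sw <- vapply(list(x, y), function(v) {
    if (stats::sd(v) == 0) return(0)  # degenerate sample: treat as non-normal
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  normal <- all(sw > alpha_normality)
  if (normal) {
    ht <- stats::t.test(x, y, var.equal = var_equal)
    test_name <- "t"
    reason <- sprintf("Shapiro-Wilk non-rejecting in both groups (p = %.3g, %.3g)",
                      sw[1], sw[2])
  } else {
    ht <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    test_name <- "MannWhitney"
    reason <- sprintf("Shapiro-Wilk rejected normality (p = %.3g, %.3g)",
                      sw[1], sw[2])
  }
  structure(list(
    test_name = test_name,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    means = c(x = mean(x), y = mean(y)),
    sds = c(x = stats::sd(x), y = stats::sd(y)),
    n = c(x = length(x), y = length(y)),
    shapiro_p = sw,
    routing_reason = reason
  ), class = "group_comparison")
}

#' Pearson chi-square test of independence on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) chi-square with one degree
#' of freedom, equal to the closed form
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.
#'
#' @param table 2x2 matrix of nonnegative integer counts with all margins
#'   positive.
#' @return List with `statistic`, `p_value`, `df` and `expected`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) ||
      any(table != round(table))) {
    artix_error("artix_bad_input",
                "a 2x2 matrix of nonnegative integer counts is required")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    artix_error("artix_zero_margin", "all table margins must be positive")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), expected = ht$expected)
}

#' Exact McNemar test for paired binary outcomes
#'
#' Two-tailed exact binomial test on the discordant pairs (e.g. returned to
#' baseline by the redness score but not by thermography).
#'
#' @param x,y Paired logical vectors.
#' @return List with `p_value`, `discordant` (counts `b` = x-only and `c` =
#'   y-only) and `n_pairs`. With zero discordant pairs, `p_value` is 1 with
#'   a warning.
#' @export
mcnemar_exact <- function(x, y) {
  stopifnot(length(x) == length(y), is.logical(x), is.logical(y))
  b <- sum(x & !y); cc <- sum(!x & y)
  if (b + cc == 0L) {
    artix_warn("artix_no_discordant",
               "no discordant pairs; McNemar p-value is 1 by convention")
    p <- 1
  } else {
    p <- stats::binom.test(b, b + cc, p = 0.5)$p.value
  }
  list(p_value = p, discordant = c(b = b, c = cc), n_pairs = length(x))
}

#' Correlation between two continuous variables
#'
#' @param x,y Numeric vectors (n >= 4), non-constant.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `r`, `p_value`, `method` and `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) {
    artix_error("artix_bad_input", "at least 4 complete pairs are required")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    artix_error("artix_constant_input", "correlation of a constant is undefined")
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ht$estimate), p_value = ht$p.value, method = method,
       n = length(x))
}

#' Multilinear regression with collinearity screening
#'
#' Checks the predictor matrix for perfect collinearity (error naming the
#' offending columns), computes variance inflation factors, drops
#' predictors with VIF above `vif_threshold`, and fits an ordinary
#' least-squares regression on the survivors.
#'
#' @param outcome Numeric response.
#' @param predictors Data frame of predictors (numeric or factor).
#' @param vif_threshold Predictors with VIF above this are rejected before
#'   the final fit.
#' @return An object of class `regression_result`: list with
#'   `coefficients` (data frame: term, B, p), `vif` (named, for screened
#'   predictors), `dropped` and the underlying `fit`.
#' @export
fit_regression <- function(outcome, predictors, vif_threshold = 10) {
  stopifnot(is.data.frame(predictors), nrow(predictors) == length(outcome))
  if (length(outcome) <= ncol(predictors) + 1L) {
    artix_error("artix_bad_input", "need n > number of predictors + 1")
  }
  dat <- cbind(data.frame(.y = outcome), predictors)
  fit0 <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit0)))) {
    bad <- names(stats::coef(fit0))[is.na(stats::coef(fit0))]
    artix_error("artix_collinear",
                paste("collinear predictors:", paste(bad, collapse = ", ")))
  }
  vifs <- if (ncol(predictors) >= 2L) {
    v <- car::vif(fit0)
    if (is.matrix(v)) stats::setNames(v[, 1], rownames(v)) else v
  } else stats::setNames(1, names(predictors))
  dropped <- names(vifs)[vifs > vif_threshold]
  kept <- setdiff(names(predictors), dropped)
  if (length(kept) == 0L) {
    artix_error("artix_collinear", "all predictors exceed the VIF threshold")
  }
  fit <- if (length(dropped) > 0L) {
    stats::lm(.y ~ ., data = dat[, c(".y", kept), drop = FALSE])
  } else fit0
  ct <- summary(fit)$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(ct), B = ct[, 1],
                              p = ct[, 4], row.names = NULL,
                              stringsAsFactors = FALSE),
    vif = vifs, dropped = dropped, fit = fit
  ), class = "regression_result")
}

#' ROC analysis of a two-class score
#'
#' Empirical ROC with trapezoidal AUC, a 95% DeLong (or bootstrap)
#' confidence interval, and the operating point maximizing Youden's J, at
#' which sensitivity, specificity and the confusion matrix are reported.
#' Lower scores indicate the positive class by default (poorer perfusion in
#' patients); set `direction = "higher"` for the opposite orientation.
#'
#' @param scores Numeric score per subject.
#' @param labels Class label per subject.
#' @param positive_class Label of the positive (patient) class.
#' @param direction `"lower"` if low scores indicate the positive class.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @return An object of class `roc_result`: list with `auc`, `ci95_low`,
#'   `ci95_high`, `threshold`, `sensitivity`, `specificity` (percentages)
#'   and `confusion` (tp, fp, fn, tn).
#' @export
roc_analysis <- function(scores, labels, positive_class = "RP",
                         direction = c("lower", "higher"),
                         ci_method = c("delong", "bootstrap")) {
  direction <- match.arg(direction)
  ci_method <- match.arg(ci_method)
  labels <- as.character(labels)
  pos <- labels == positive_class
  if (!any(pos) || all(pos)) {
    artix_error("artix_bad_input", "both classes must be present")
  }
  dir_sym <- if (direction == "lower") ">" else "<"
  roc <- pROC::roc(response = factor(pos, levels = c(FALSE, TRUE)),
                   predictor = scores, direction = dir_sym,
                   levels = c(FALSE, TRUE), quiet = TRUE)
  auc <- as.numeric(pROC::auc(roc))
  ci <- if (ci_method == "delong") {
    suppressWarnings(as.numeric(pROC::ci.auc(roc, method = "delong")))
  } else {
    as.numeric(pROC::ci.auc(roc, method = "bootstrap", boot.n = 2000,
                            progress = "none"))
  }
  best <- pROC::coords(roc, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, , drop = FALSE]
  thr <- best$threshold
  pred_pos <- if (direction == "lower") scores <= thr else scores >= thr
  confusion <- c(tp = sum(pred_pos & pos), fp = sum(pred_pos & !pos),
                 fn = sum(!pred_pos & pos), tn = sum(!pred_pos & !pos))
  structure(list(
    auc = auc, ci95_low = min(ci), ci95_high = max(ci),
    threshold = thr,
    sensitivity = 100 * confusion[["tp"]] / sum(pos),
    specificity = 100 * confusion[["tn"]] / sum(!pos),
    confusion = confusion, ci_method = ci_method, direction = direction
  ), class = "roc_result")
}

#' Multi-group comparison utility
#'
#' Thin wrapper over one-way ANOVA with Bonferroni-corrected pairwise
#' t-tests (normally distributed data) or Kruskal-Wallis with
#' Bonferroni-corrected pairwise Wilcoxon tests as the rank-based post hoc.
#'
#' @param values Numeric vector.
#' @param groups Factor with 3 or more levels.
#' @param normal Whether to use the parametric route.
#' @return List with `test`, `p_value` and `posthoc` (pairwise p matrix).
#' @export
compare_multi <- function(values, groups, normal = TRUE) {
  groups <- droplevels(as.factor(groups))
  stopifnot(nlevels(groups) >= 3L)
  if (normal) {
    fit <- stats::aov(values ~ groups)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    ph <- stats::pairwise.t.test(values, groups, p.adjust.method = "bonferroni")
    list(test = "anova", p_value = p, posthoc = ph$p.value)
  } else {
    kw <- stats::kruskal.test(values, groups)
    ph <- suppressWarnings(
      stats::pairwise.wilcox.test(values, groups,
                                  p.adjust.method = "bonferroni"))
    list(test = "kruskal", p_value = kw$p.value, posthoc = ph$p.value)
  }
}
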