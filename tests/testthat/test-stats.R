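test_that("group comparison routes through normality and records why", {
  set.seed(11)
  x <- rnorm(30)
  same <- compare_groups(x, x)
  expect_equal(same$test_name, "t")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_match(same$routing_reason, "non-rejecting")

  set.seed(12)
  ln <- exp(rnorm(50, 0, 1))
  cmp <- compare_groups(ln, rnorm(50))
  expect_equal(cmp$test_name, "MannWhitney")

  set.seed(11)
  strong <- compare_groups(rnorm(30, 0, 1), rnorm(30, 2, 1))
  expect_lt(strong$p_value, 0.001)

  expect_error(compare_groups(1:2, 1:10), class = "artix_bad_input")
})

test_that("chi-square matches its closed form and handles degenerate tables", {
  closed_form <- function(t) {
    n <- sum(t)
    n * (t[1, 1] * t[2, 2] - t[1, 2] * t[2, 1])^2 /
      (sum(t[1, ]) * sum(t[2, ]) * sum(t[, 1]) * sum(t[, 2]))
  }
  set.seed(21)
  for (i in 1:50) {
    tb <- matrix(sample(1:40, 4, replace = TRUE), 2)
    res <- chi_square_2x2(tb)
    expect_equal(res$statistic, closed_form(tb), tolerance = 1e-9)
  }
  bal <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p_value, 1)
  sep <- chi_square_2x2(matrix(c(20, 0, 0, 20), 2))
  expect_equal(sep$statistic, 40)
  expect_lt(sep$p_value, 1e-9)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               class = "artix_zero_margin")
})

test_that("exact McNemar equals the binomial tail sum on discordant pairs", {
  mk <- function(b, cc, n = 40) {
    x <- rep(FALSE, n); y <- rep(FALSE, n)
    x[seq_len(b)] <- TRUE
    y[b + seq_len(cc)] <- TRUE
    both <- b + cc + seq_len(n - b - cc)
    x[both] <- TRUE; y[both] <- TRUE
    list(x = x, y = y)
  }
  sym <- mk(10, 10)
  expect_equal(mcnemar_exact(sym$x, sym$y)$p_value, 1)
  skew <- mk(9, 1)
  expect_equal(mcnemar_exact(skew$x, skew$y)$p_value,
               2 * (choose(10, 0) + choose(10, 1)) / 2^10,
               tolerance = 1e-12)
  conc <- mk(0, 0)
  expect_warning(res <- mcnemar_exact(conc$x, conc$y),
                 class = "artix_no_discordant")
  expect_equal(res$p_value, 1)
})

test_that("correlation distinguishes rank from linear association", {
  x <- seq(-2, 2, length.out = 40)
  expect_equal(correlate(x, x, "pearson")$r, 1)
  expect_equal(correlate(x, x, "spearman")$r, 1)
  cub <- x^3
  expect_equal(correlate(x, cub, "spearman")$r, 1)
  expect_lt(correlate(x, cub, "pearson")$r, 1)
  set.seed(31)
  ind <- correlate(rnorm(1000), rnorm(1000), "pearson")
  expect_lt(abs(ind$r), 0.1)
  expect_error(correlate(rep(1, 10), rnorm(10)),
               class = "artix_constant_input")
})

test_that("regression screens collinearity and recovers coefficients", {
  n <- 40
  preds <- data.frame(a = rep(c(-1, 1), n / 2),
                      b = rep(c(-1, -1, 1, 1), n / 4))
  set.seed(41)
  y <- rnorm(n)
  res <- fit_regression(y, preds)
  expect_true(all(abs(res$vif - 1) < 1e-9))

  dup <- preds; dup$c <- dup$a
  expect_error(fit_regression(y, dup), class = "artix_collinear")

  set.seed(5)
  x1 <- rnorm(200)
  y2 <- 10 + 14 * x1 + rnorm(200, 0, 1)
  res2 <- fit_regression(y2, data.frame(x1 = x1))
  b1 <- res2$coefficients$B[res2$coefficients$term == "x1"]
  expect_gt(b1, 12); expect_lt(b1, 16)
})

test_that("ROC analysis orientation, operating point and AUC identity", {
  sep <- roc_analysis(c(1, 2, 3, 10, 11, 12), rep(c("RP", "HC"), each = 3))
  expect_equal(sep$auc, 1)
  expect_equal(sep$sensitivity, 100)
  expect_equal(sep$specificity, 100)
  expect_equal(unname(sep$confusion), c(3L, 0L, 0L, 3L))

  lo <- roc_analysis(1:4, c("RP", "RP", "HC", "HC"), direction = "lower")
  hi <- roc_analysis(1:4, c("RP", "RP", "HC", "HC"), direction = "higher")
  expect_equal(lo$auc, 1)
  expect_equal(hi$auc, 0)

  # AUC equals the Mann-Whitney U statistic divided by n1 n2
  set.seed(51)
  for (i in 1:20) {
    n1 <- sample(8:25, 1); n2 <- sample(8:25, 1)
    s <- c(rnorm(n1, 0), rnorm(n2, 1))
    lab <- c(rep("RP", n1), rep("HC", n2))
    auc <- roc_analysis(s, lab, direction = "lower")$auc
    u <- wilcox.test(s[lab == "HC"], s[lab == "RP"], exact = FALSE)$statistic
    expect_equal(auc, unname(u) / (n1 * n2), tolerance = 1e-9)
  }

  expect_error(roc_analysis(1:4, rep("RP", 4)), class = "artix_bad_input")
  # DeLong interval brackets the point estimate
  set.seed(52)
  r <- roc_analysis(c(rnorm(30, 0), rnorm(30, 1)),
                    rep(c("RP", "HC"), each = 30), direction = "lower")
  expect_lte(r$ci95_low, r$auc); expect_gte(r$ci95_high, r$auc)
})

test_that("cohort report covers every timepoint and is reproducible", {
  co <- generate_cohort(12, 10, seed = 8)
  rep1 <- suppressWarnings(cohort_report(co))
  g <- rep1$strata$global
  expect_length(g$per_timepoint, 7L)
  expect_true(all(vapply(g$per_timepoint,
                         function(x) inherits(x$roc, "roc_result"),
                         logical(1))))
  rep2 <- suppressWarnings(cohort_report(generate_cohort(12, 10, seed = 8)))
  expect_identical(report_to_json(rep1), report_to_json(rep2))

  # a season stratum holding a single group is skipped with a warning;
  # here SepDec contains patients only while MayJul holds both groups
  sess <- co$sessions
  is_rp <- vapply(sess, function(s) s$group == "RP", logical(1))
  for (i in seq_along(sess)) {
    sess[[i]]$season <- if (is_rp[i] && i %% 2 == 0) "SepDec" else "MayJul"
  }
  expect_warning(r3 <- cohort_report(sess), class = "artix_stratum_skipped")
  expect_false("SepDec" %in% names(r3$strata) && !is.null(r3$strata$SepDec))
  expect_s3_class(rep1, "analysis_report")
})

test_that("multi-group utilities route parametric and rank-based paths", {
  set.seed(61)
  g <- factor(rep(c("early", "active", "late"), each = 15))
  v <- rnorm(45, mean = as.integer(g))
  par <- compare_multi(v, g, normal = TRUE)
  expect_equal(par$test, "anova")
  expect_lt(par$p_value, 0.01)
  rnk <- compare_multi(v, g, normal = FALSE)
  expect_equal(rnk$test, "kruskal")
  expect_lt(rnk$p_value, 0.01)
})
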