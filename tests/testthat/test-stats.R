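test_that("Spearman R matches the rank formula and the t-approximation", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  res <- spearman_cor(x, y, exact = FALSE)
  # no ties: R = 1 - 6*sum(d^2)/(n(n^2-1))
  d <- rank(x) - rank(y)
  expect_equal(res$estimate, 1 - 6 * sum(d^2) / (5 * 24))
  # independent cross-check against base R
  base <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(res$estimate, unname(base$estimate))

  expect_equal(spearman_cor(1:8, (1:8)^3, exact = FALSE)$estimate, 1)
  expect_equal(spearman_cor(1:8, -(1:8)^3, exact = FALSE)$estimate, -1)

  # t-approximation p at cohort scale agrees with base R's t fallback
  set.seed(12)
  a <- rnorm(60); b <- 0.5 * a + rnorm(60)
  ours <- spearman_cor(a, b)
  base2 <- cor.test(a, b, method = "spearman", exact = FALSE)
  expect_equal(ours$p.value, base2$p.value, tolerance = 1e-10)
  expect_equal(ours$estimate, unname(base2$estimate))
})

test_that("exact permutation p-value equals brute-force enumeration", {
  cases <- list(
    list(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5)),
    list(x = c(3, 1, 4, 1, 5), y = c(2, 7, 1, 8, 2)),   # ties in both
    list(x = 1:6, y = c(2, 4, 1, 3, 6, 5)))
  for (cs in cases) {
    res <- spearman_cor(cs$x, cs$y, exact = TRUE)
    expect_equal(res$p.value, perm_pvalue_oracle(cs$x, cs$y),
                 tolerance = 1e-12)
  }
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(99)
  for (i in 1:5) {
    x <- rnorm(20); y <- rnorm(20)
    r0 <- spearman_cor(x, y)$estimate
    expect_equal(spearman_cor(exp(x), y)$estimate, r0)
    expect_equal(spearman_cor(x, 3 * y + 2)$estimate, r0)
    expect_equal(spearman_cor(-1 / (x - min(x) + 1), y)$estimate, r0)
  }
  expect_error(spearman_cor(rep(1, 5), 1:5), class = "lungdens_stats_error")
})

test_that("interpretation bands follow the stated cutpoints", {
  expect_equal(interpret_r(-0.65), "good")
  expect_equal(interpret_r(0.20), "absent to weak")
  expect_equal(interpret_r(0.85), "strong")
  expect_equal(interpret_r(0.39), "absent to weak")
  expect_equal(interpret_r(0.40), "moderate")
  expect_equal(interpret_r(0.59), "moderate")
  expect_equal(interpret_r(-0.60), "good")
  expect_equal(interpret_r(0.79), "good")
  expect_equal(interpret_r(0.80), "strong")
  expect_error(interpret_r(1.3), class = "lungdens_validation_error")
})

test_that("signed-rank test matches exhaustive enumeration for n = 6", {
  a <- c(5.1, 6.2, 4.8, 7.0, 5.5, 6.6)
  # constant positive offset: minimal one-sided statistic
  b <- a + 2
  res <- wilcoxon_paired(a, b)
  expect_equal(res$statistic, 0)
  expect_equal(res$method, "exact")
  expect_equal(res$p.value, signrank_pvalue_oracle(a - b))
  expect_equal(res$p.value, 2 / 2^6)

  # mixed-sign differences
  b2 <- a + c(0.3, -0.8, 0.2, -0.1, 0.5, -0.9)
  res2 <- wilcoxon_paired(a, b2)
  expect_equal(res2$p.value, signrank_pvalue_oracle(a - b2))
  # antisymmetric differences sit in the p ~ 1 region
  b3 <- a + c(0.4, -0.4, 0.3, -0.3, 0.2, -0.2)
  res3 <- wilcoxon_paired(a, b3)
  expect_equal(res3$p.value, signrank_pvalue_oracle(a - b3))
  expect_gt(res3$p.value, 0.8)

  # base R as an independent cross-check (no ties -> both exact)
  expect_equal(res2$p.value, wilcox.test(a, b2, paired = TRUE)$p.value)
})

test_that("tied magnitudes keep an exact conditional p at small n", {
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  b <- c(2, 1, 4, 3, 7, 5, 6, 10)   # |d| has ties
  res <- wilcoxon_paired(a, b)
  expect_equal(res$method, "exact")
  expect_equal(res$p.value, signrank_pvalue_oracle(a - b), tolerance = 1e-12)
  expect_error(wilcoxon_paired(a, a), class = "lungdens_stats_error")
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(61)
  a <- round(rnorm(30, 10, 2), 1)
  b <- round(a + rnorm(30, 0.6, 1), 1)  # rounding induces tied |d|
  b[b == a] <- a[b == a] + 0.05         # keep all differences nonzero
  res <- wilcoxon_paired(a, b)
  expect_match(res$method, "normal")
  ref <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                      correct = FALSE))
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("ICC(2,1) matches the ANOVA mean-squares oracle", {
  m <- cbind(r1 = c(8, 6, 7, 9, 5), r2 = c(7, 6, 8, 9, 6))
  res <- icc_agreement(m)
  # independent oracle: mean squares from base R aov()
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(1:5, 2)),
                   rater = factor(rep(1:2, each = 5)))
  ms <- summary(aov(y ~ subject + rater, df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_oracle <- (msr - mse) / (msr + (2 - 1) * mse + 2 * (msc - mse) / 5)
  expect_equal(res$icc, icc_oracle, tolerance = 1e-12)
  expect_true(res$defined)

  # identical raters agree perfectly
  expect_equal(icc_agreement(cbind(1:5, 1:5))$icc, 1)
  # opposed raters on centred scores disagree below zero
  x <- c(-2, -1, 0, 1, 2)
  expect_lt(icc_agreement(cbind(x, -x))$icc, 0)
  # no variance anywhere -> undefined, not 1
  flat <- icc_agreement(cbind(rep(3, 4), rep(3, 4)))
  expect_false(flat$defined)
  expect_true(is.na(flat$icc))
  # rater relabeling leaves ICC unchanged
  expect_equal(icc_agreement(m[, 2:1])$icc, res$icc)
})

test_that("Bland-Altman bias and limits follow the sample-SD formulas", {
  a <- c(10, 12, 9, 14, 11)
  expect_equal(tidy(bland_altman(a, a)),
               tibble::tibble(bias = 0, sd_diff = 0, loa_lower = 0,
                              loa_upper = 0, n = 5L))
  res <- bland_altman(a, a - 3)
  expect_equal(res$bias, 3)
  expect_equal(res$loa_upper - res$loa_lower, 0)

  set.seed(4)
  x <- rnorm(12, 20, 3); y <- x + rnorm(12, 1, 0.8)
  res2 <- bland_altman(x, y)
  d <- x - y
  expect_equal(res2$bias, mean(d))
  expect_equal(res2$loa_lower, mean(d) - 1.96 * sd(d))
  expect_equal(res2$loa_upper, mean(d) + 1.96 * sd(d))
  # antisymmetry under swapping the raters
  expect_equal(bland_altman(y, x)$bias, -res2$bias)
  expect_error(bland_altman(1, numeric(0)),
               class = "lungdens_validation_error")
})

test_that("Bhalla totals validate ranges and aggregate monotonically", {
  rub <- bhalla_rubric()
  expect_equal(nrow(rub), 9)
  zero <- stats::setNames(rep(0, 9), rub$category)
  expect_equal(bhalla_total(zero), 0)  # normal scan

  full <- stats::setNames(rub$max, rub$category)
  expect_equal(bhalla_total(full), sum(rub$max))

  bad <- zero; bad["emphysema"] <- 3  # above its 0-2 range
  expect_error(bhalla_total(bad), "emphysema",
               class = "lungdens_validation_error")

  # monotone non-decreasing in every category
  for (cat_i in rub$category) {
    lo <- zero
    hi <- zero; hi[cat_i] <- rub$max[rub$category == cat_i]
    expect_gte(bhalla_total(hi), bhalla_total(lo))
  }
})
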