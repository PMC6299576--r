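#' Spearman rank correlation with interpretation band
#'
#' R is the Pearson correlation of midranks. The two-sided p-value comes
#' from the t approximation `t = R * sqrt((n-2) / (1-R^2))` on `n - 2`
#' degrees of freedom, adequate for cohort-sized n; for `n <= 10` an exact
#' permutation p-value (all distinct permutations of one rank vector) is
#' available and used automatically when `exact = NULL`.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`; ties receive
#'   midranks. (For the `tidy()` method, `x` is a `ct_cor` object.)
#' @param exact Force (`TRUE`)/suppress (`FALSE`) the exact permutation
#'   p-value; `NULL` chooses exact for `n <= 10`.
#' @return A `ct_cor` object: `estimate`, `p.value`, `n`, `band`,
#'   `method`. [tidy()] returns it as a one-row tibble.
#' @export
#' @examples
#' spearman_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
spearman_cor <- function(x, y, exact = NULL) {
  check_pair(x, y, min_n = 3L)
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Spearman correlation undefined: an input vector is constant.",
          class = "lungdens_stats_error")
  }
  n <- length(x)
  rx <- rank(x)  # midranks for ties
  ry <- rank(y)
  r <- cor(rx, ry)
  use_exact <- if (is.null(exact)) n <= 10L else isTRUE(exact)
  if (use_exact && n > 10L) {
    abort("Exact permutation p-value only supported for n <= 10.",
          class = "lungdens_stats_error")
  }
  if (use_exact) {
    p <- .spearman_perm_pvalue(rx, ry)
    method <- "exact permutation"
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  structure(list(estimate = r, p.value = min(p, 1), n = n,
                 band = interpret_r(r), method = method),
            class = "ct_cor")
}

#' @export
print.ct_cor <- function(x, ...) {
  cat(sprintf("Spearman R = %.3f (%s), p = %.4g, n = %d [%s]\n",
              x$estimate, x$band, x$p.value, x$n, x$method))
  invisible(x)
}

#' @rdname spearman_cor
#' @param ... Unused.
#' @export
tidy.ct_cor <- function(x, ...) {
  tibble(estimate = x$estimate, p.value = x$p.value, n = x$n,
         band = x$band, method = x$method)
}

#' Interpretation band for a correlation coefficient
#'
#' Bands the magnitude of a rank correlation: |R| < 0.4 "absent to weak",
#' 0.40-0.59 "moderate", 0.60-0.79 "good", 0.8 and above "strong".
#'
#' @param r Correlation in `[-1, 1]`.
#' @return Band label (character).
#' @export
#' @examples
#' interpret_r(-0.65)  # "good"
interpret_r <- function(r) {
  if (!is.finite(r) || abs(r) > 1 + 1e-12) {
    abort("`r` must lie in [-1, 1].", class = "lungdens_validation_error")
  }
  a <- abs(r)
  if (a < 0.4) "absent to weak"
  else if (a < 0.6) "moderate"
  else if (a < 0.8) "good"
  else "strong"
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank statistic `V` = sum of ranks of positive differences,
#' computed on the nonzero differences with midranks for tied magnitudes.
#' For `n <= 25` nonzero pairs the two-sided p-value is exact: the full
#' sign-flip distribution of `V` conditional on the observed `|d|` ranks,
#' built by generating-function convolution (equivalent to enumerating all
#' `2^n` sign patterns, and identical to the classical signed-rank
#' distribution when the ranks are untied). Beyond that, a normal
#' approximation with tie correction (no continuity correction) is used.
#'
#' @param a,b Equal-length paired numeric vectors.
#' @return List with `statistic` (V), `p.value`, `n` (nonzero pairs),
#'   `method`.
#' @export
wilcoxon_paired <- function(a, b) {
  check_pair(a, b, min_n = 1L)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    abort("All paired differences are zero; signed-rank test undefined.",
          class = "lungdens_stats_error")
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25L) {
    # distribution of V over all 2^n sign patterns, on doubled ranks so
    # midranks stay integral
    r2 <- as.integer(round(2 * r))
    f <- c(1, numeric(sum(r2)))
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(length(f) - ri)])
      f <- f + shifted
    }
    probs <- f / 2^n
    v2 <- as.integer(round(2 * V))
    p <- 2 * min(sum(probs[seq_len(v2 + 1L)]),
                 sum(probs[seq.int(v2 + 1L, length(probs))]))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  list(statistic = V, p.value = min(p, 1), n = n, method = method)
}

#' Intraclass correlation for two raters, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC from the
#' ANOVA mean squares of the subjects-by-raters table:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param ratings Matrix or data frame, `n >= 3` subjects by `k = 2`
#'   raters, no missing cells.
#' @return List: `icc`, `n`, `k`, the mean squares, and `defined`
#'   (`FALSE` with `icc = NA` when between-subject variance is zero).
#' @export
#' @examples
#' icc_agreement(cbind(c(8, 6, 7, 9, 5), c(7, 6, 8, 9, 6)))
icc_agreement <- function(ratings) {
  m <- as.matrix(ratings)
  if (anyNA(m)) {
    abort("Ratings table has missing cells.", class = "lungdens_stats_error")
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 3L || k < 2L) {
    abort("Need at least 3 subjects and 2 raters.",
          class = "lungdens_stats_error")
  }
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  # no variance anywhere in the table -> ICC undefined, never silently 1 or 0
  if (sst <= .Machine$double.eps || denom == 0) {
    return(list(icc = NA_real_, n = n, k = k, msr = msr, msc = msc,
                mse = mse, defined = FALSE))
  }
  list(icc = (msr - mse) / denom, n = n, k = k, msr = msr, msc = msc,
       mse = mse, defined = TRUE)
}

#' Bland-Altman agreement analysis
#'
#' Bias is `mean(a - b)`; the limits of agreement are
#' `bias +/- 1.96 * SD(a - b)` with the sample (n-1) SD, the conventional
#' choice for limits of agreement.
#'
#' @param a,b Equal-length paired measurements, `n >= 2`.
#' @return A `bland_altman` object: `bias`, `loa_lower`, `loa_upper`,
#'   `sd_diff`, `n`, and `data` (tibble of pair means vs differences for
#'   plotting). `tidy()` and `autoplot()` methods are provided.
#' @export
bland_altman <- function(a, b) {
  check_pair(a, b, min_n = 2L)
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  structure(
    list(bias = bias, sd_diff = s,
         loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
         n = length(d),
         data = tibble(mean = (a + b) / 2, diff = d)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, limits of agreement [%.3f, %.3f], n = %d\n",
              x$bias, x$loa_lower, x$loa_upper, x$n))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff, loa_lower = x$loa_lower,
         loa_upper = x$loa_upper, n = x$n)
}

#' @rdname bland_altman
#' @param object A `bland_altman` object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = 2) +
    ggplot2::labs(x = "Mean of raters", y = "Difference",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Bhalla visual-score aggregation
#'
#' The Bhalla system scores nine CT abnormality categories (severity and
#' extent of bronchiectasis, peribronchial thickening, mucus plugging,
#' sacculations, airway generations involved, bullae, emphysema,
#' collapse/consolidation) on small integer scales. The category
#' definitions and admissible ranges are configuration data
#' ([bhalla_rubric()]); the total used here is the plain sum of subscores,
#' so it is monotone non-decreasing in each category and 0 for a normal
#' scan.
#'
#' @param subscores Named numeric vector, data frame row, or list of the 9
#'   category subscores.
#' @param rubric Rubric configuration, see [bhalla_rubric()].
#' @return Total score (numeric scalar).
#' @export
#' @examples
#' sc <- setNames(rep(0, 9), bhalla_rubric()$category)
#' bhalla_total(sc)  # normal scan -> 0
bhalla_total <- function(subscores, rubric = bhalla_rubric()) {
  sc <- unlist(subscores)
  missing_c <- setdiff(rubric$category, names(sc))
  if (length(missing_c)) {
    abort(sprintf("Missing Bhalla categor%s: %s",
                  if (length(missing_c) > 1) "ies" else "y",
                  paste(missing_c, collapse = ", ")),
          class = "lungdens_validation_error")
  }
  sc <- sc[rubric$category]
  bad <- sc != round(sc) | sc < rubric$min | sc > rubric$max
  if (any(bad)) {
    abort(sprintf("Bhalla subscore out of range for: %s",
                  paste(rubric$category[bad], collapse = ", ")),
          class = "lungdens_validation_error")
  }
  sum(sc)
}

#' @rdname bhalla_total
#' @export
bhalla_rubric <- function() {
  tibble(
    category = c("bronchiectasis_severity", "peribronchial_thickening",
                 "bronchiectasis_extent", "mucus_plugging_extent",
                 "sacculations", "generations_involved", "bullae",
                 "emphysema", "collapse_consolidation"),
    min = 0L,
    max = c(3L, 3L, 3L, 3L, 3L, 3L, 3L, 2L, 2L))
}

check_pair <- function(a, b, min_n = 2L) {
  if (length(a) != length(b)) {
    abort("Paired vectors must have equal length.",
          class = "lungdens_validation_error")
  }
  if (length(a) < min_n) {
    abort(sprintf("Need at least %d observations.", min_n),
          class = "lungdens_validation_error")
  }
  if (anyNA(a) || anyNA(b)) {
    abort("Inputs must not contain NA.", class = "lungdens_validation_error")
  }
  invisible(TRUE)
}
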