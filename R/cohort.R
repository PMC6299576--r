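#' Correlation matrix of features/scores against spirometry
#'
#' For every variable in `vars`, computes the Spearman correlation (with
#' p-value and interpretation band) against every spirometric column in
#' `against` — the cohort-level association table relating histogram
#' characteristics and CT-density scores to FEV1/FVC %predicted. A
#' constant variable is reported as a flagged row (`defined = FALSE`)
#' rather than aborting the run.
#'
#' @param data Cohort data frame (e.g. from [score_cohort()]).
#' @param vars Character vector of feature/score column names; defaults to
#'   every numeric column except `against` and the simulation bookkeeping
#'   columns (`phantom_seed`, the ground-truth `lesion_fraction`).
#' @param against Spirometry column names, default `c("fev1", "fvc")`.
#' @return Tibble: `variable`, `against`, `r`, `p.value`, `n`, `band`,
#'   `defined`.
#' @export
cohort_correlations <- function(data, vars = NULL,
                                against = c("fev1", "fvc")) {
  stopifnot(is.data.frame(data))
  missing_a <- setdiff(against, names(data))
  if (length(missing_a)) {
    abort(sprintf("Cohort table lacks column(s): %s",
                  paste(missing_a, collapse = ", ")),
          class = "lungdens_validation_error")
  }
  if (is.null(vars)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    vars <- setdiff(num, c(against, "phantom_seed", "lesion_fraction"))
  }
  if (nrow(data) < 3L) {
    abort("Need at least 3 complete subjects.",
          class = "lungdens_validation_error")
  }
  grid <- tidyr::expand_grid(variable = vars, against = against)
  purrr::pmap_dfr(grid, function(variable, against) {
    x <- data[[variable]]; y <- data[[against]]
    ok <- stats::complete.cases(x, y)
    res <- tryCatch(spearman_cor(x[ok], y[ok], exact = FALSE),
                    error = function(e) NULL)
    if (is.null(res)) {
      tibble(variable = variable, against = against, r = NA_real_,
             p.value = NA_real_, n = sum(ok), band = NA_character_,
             defined = FALSE)
    } else {
      tibble(variable = variable, against = against, r = res$estimate,
             p.value = res$p.value, n = res$n, band = res$band,
             defined = TRUE)
    }
  })
}

#' Upper-versus-lower regional comparison
#'
#' Paired Wilcoxon signed-rank comparison of regional CT-density scores,
#' with medians and interquartile ranges per region — the standard summary
#' for asking whether disease burden concentrates in the lower lungs.
#'
#' @param data Cohort data frame with `upper_score` and `lower_score`
#'   columns (see [score_cohort()]).
#' @return One-row tibble: medians, IQRs, Wilcoxon `statistic`, `p.value`,
#'   `n`.
#' @export
compare_upper_lower <- function(data) {
  need <- c("upper_score", "lower_score")
  if (!all(need %in% names(data))) {
    abort("Cohort table needs `upper_score` and `lower_score` columns.",
          class = "lungdens_validation_error")
  }
  up <- data$upper_score; lo <- data$lower_score
  w <- wilcoxon_paired(lo, up)
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  qu <- qs(up); ql <- qs(lo)
  tibble(upper_median = qu[2], upper_iqr_lo = qu[1], upper_iqr_hi = qu[3],
         lower_median = ql[2], lower_iqr_lo = ql[1], lower_iqr_hi = ql[3],
         statistic = w$statistic, p.value = w$p.value, n = w$n,
         method = w$method)
}

#' Interobserver agreement of visual scores
#'
#' ICC(2,1) and Bland-Altman agreement between two raters' visual score
#' columns.
#'
#' @param data Data frame holding both raters' totals.
#' @param rater1,rater2 Column names.
#' @return List with `icc` (from [icc_agreement()]) and `bland_altman`
#'   (from [bland_altman()]); `glance()` flattens both to one row.
#' @export
rater_agreement <- function(data, rater1, rater2) {
  miss <- setdiff(c(rater1, rater2), names(data))
  if (length(miss)) {
    abort(sprintf("Missing rater column(s): %s", paste(miss, collapse = ", ")),
          class = "lungdens_validation_error")
  }
  a <- data[[rater1]]; b <- data[[rater2]]
  structure(list(icc = icc_agreement(cbind(a, b)), bland_altman = bland_altman(a, b)),
            class = "rater_agreement")
}

#' @rdname rater_agreement
#' @param x A `rater_agreement` object.
#' @param ... Unused.
#' @export
glance.rater_agreement <- function(x, ...) {
  tibble(icc = x$icc$icc, icc_defined = x$icc$defined,
         bias = x$bland_altman$bias,
         loa_lower = x$bland_altman$loa_lower,
         loa_upper = x$bland_altman$loa_upper, n = x$bland_altman$n)
}

#' @export
print.rater_agreement <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %s\n",
              if (x$icc$defined) sprintf("%.3f", x$icc$icc) else "undefined"))
  print(x$bland_altman)
  invisible(x)
}

#' Plot CT-density score against a spirometric variable
#'
#' @param data Cohort data frame.
#' @param score Score column name (default the MLD+1SD suite column).
#' @param against Spirometry column (default `fev1`).
#' @return A ggplot.
#' @export
plot_score_vs_spirometry <- function(data, score = "score_MLD+1SD",
                                     against = "fev1") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[score]],
                                     y = .data[[against]])) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "grey40") +
    ggplot2::labs(x = sprintf("CT-density score (%s)",
                              sub("^score_", "", score)),
                  y = paste(toupper(against), "(% predicted)")) +
    ggplot2::theme_minimal()
}
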