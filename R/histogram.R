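#' Lung density histogram
#'
#' Histogram of HU values over a masked region, with uniform half-open
#' bins `[lo, hi)` aligned to integer multiples of the bin width. A value
#' lying exactly on an interior edge falls in the right-hand bin.
#'
#' @param vol A [ct_volume()].
#' @param mask A [lung_mask()] on the same grid.
#' @param region Region selector (see [lung_mask()]).
#' @param bin_width Bin width in HU; default 1 HU (CT values are
#'   near-integer).
#' @return A `density_histogram`: tibble of `(lo, hi, mid, count)` with
#'   attributes `bin_width`, `n` and `region`.
#' @export
compute_histogram <- function(vol, mask, region = "whole", bin_width = 1) {
  if (!is.finite(bin_width) || bin_width <= 0) {
    abort("`bin_width` must be > 0.", class = "lungdens_validation_error")
  }
  v <- masked_values(vol, mask, region)
  if (length(v) == 0L) {
    abort(sprintf("Region '%s' is empty.", region),
          class = "lungdens_region_error")
  }
  bins <- floor(v / bin_width)          # half-open [k*w, (k+1)*w)
  lo_k <- min(bins); hi_k <- max(bins)
  counts <- tabulate(bins - lo_k + 1L, nbins = hi_k - lo_k + 1L)
  lo <- (lo_k:hi_k) * bin_width
  out <- tibble(lo = lo, hi = lo + bin_width, mid = lo + bin_width / 2,
                count = counts)
  structure(out, bin_width = bin_width, n = length(v), region = region,
            class = c("density_histogram", class(out)))
}

#' Density-histogram characteristics of a lung region
#'
#' Computes the five histogram characteristics used to describe the lung
#' density distribution: mean lung density (MLD), mode (most represented
#' attenuation value), standard deviation (SD), skewness (asymmetry) and
#' kurtosis (sharpness). Moments are computed from the raw masked voxel
#' values; the histogram is only used for the mode.
#'
#' Structural abnormalities such as bronchial wall thickening, mucus
#' plugging and consolidation add mass to the right (dense) side of the
#' histogram, raising SD and flattening the peak (lower kurtosis).
#'
#' @inheritParams compute_histogram
#' @param kurtosis Convention: `"excess"` (fourth standardized moment
#'   minus 3; Gaussian = 0, the default) or `"moment"` (Gaussian = 3).
#' @param bin_width Bin width (HU) used for the mode.
#' @param mode_method How the mode (histogram peak) is located.
#'   `"standardized"` (default): argmax of the histogram of standardized
#'   values `(v - MLD) / SD`, bin width 1/60 in SD units (about
#'   `bin_width` HU at the typical inspiratory parenchymal SD of 60 HU),
#'   mapped back to HU. This estimator commutes exactly with affine HU
#'   changes, so Mode-anchored adapted thresholds are exactly invariant to
#'   inspiration-level shifts and spread changes. `"binned"`: classical
#'   argmax of the absolute histogram at `bin_width` HU bins aligned to
#'   integer multiples of the width. Ties are broken toward the lowest HU
#'   in both methods.
#' @details SD is the population (divide-by-n) standard deviation: regions
#'   hold 1e6-1e7 voxels so the n vs n-1 distinction is negligible, and
#'   population moments match closed-form oracles exactly. When SD is 0
#'   (constant region) skewness and kurtosis are undefined and returned as
#'   `NA` with `moments_defined = FALSE` — never silently 0, and the mode
#'   is the constant value itself.
#' @return A `hist_features` object (also a plain list): fields `mld`,
#'   `mode`, `sd`, `skewness`, `kurtosis`, `n`, `moments_defined`,
#'   `kurtosis_type`, `region`. Use [tidy()] for a one-row tibble.
#' @export
#' @examples
#' vol <- ct_volume(array(c(-900, -700), c(2, 1, 1)))
#' msk <- lung_mask(array(1L, c(2, 1, 1)), c(lung = 1))
#' tidy(compute_features(vol, msk))
compute_features <- function(vol, mask, region = "whole",
                             kurtosis = c("excess", "moment"),
                             bin_width = 1,
                             mode_method = c("standardized", "binned")) {
  kurtosis <- match.arg(kurtosis)
  mode_method <- match.arg(mode_method)
  v <- masked_values(vol, mask, region)
  if (length(v) == 0L) {
    abort(sprintf("Region '%s' is empty.", region),
          class = "lungdens_region_error")
  }
  n <- length(v)
  m <- mean(v)
  dev <- v - m
  sd_pop <- sqrt(sum(dev^2) / n)
  defined <- sd_pop > 0 && n >= 2L

  mode_hu <- if (!defined) {
    v[1]
  } else if (mode_method == "standardized") {
    # argmax on standardized values; affine-equivariant by construction
    wz <- bin_width / 60
    k <- floor(dev / sd_pop / wz)
    lo_k <- min(k)
    counts <- tabulate(k - lo_k + 1L, nbins = max(k) - lo_k + 1L)
    m + sd_pop * wz * (lo_k + which.max(counts) - 1L + 0.5)
  } else {
    h <- compute_histogram(vol, mask, region, bin_width = bin_width)
    h$mid[which.max(h$count)]  # which.max takes the first (lowest HU) tie
  }
  if (defined) {
    skew <- sum(dev^3) / n / sd_pop^3
    kurt <- sum(dev^4) / n / sd_pop^4 - if (kurtosis == "excess") 3 else 0
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  structure(
    list(mld = m, mode = mode_hu, sd = sd_pop, skewness = skew,
         kurtosis = kurt, n = n, moments_defined = defined,
         kurtosis_type = kurtosis, mode_method = mode_method,
         region = region, bin_width = bin_width),
    class = "hist_features")
}

#' @export
print.hist_features <- function(x, ...) {
  cat(sprintf("<hist_features> region '%s', n = %d voxels\n", x$region, x$n))
  cat(sprintf("  MLD %.2f HU | mode %.1f HU | SD %.2f HU\n",
              x$mld, x$mode, x$sd))
  if (x$moments_defined) {
    cat(sprintf("  skewness %.3f | kurtosis (%s) %.3f\n",
                x$skewness, x$kurtosis_type, x$kurtosis))
  } else {
    cat("  skewness/kurtosis undefined (constant region, SD = 0)\n")
  }
  invisible(x)
}

#' @rdname compute_features
#' @param x A `hist_features` object.
#' @param ... Unused.
#' @export
tidy.hist_features <- function(x, ...) {
  tibble(region = x$region, mld = x$mld, mode = x$mode, sd = x$sd,
         skewness = x$skewness, kurtosis = x$kurtosis,
         kurtosis_type = x$kurtosis_type, n_voxels = x$n,
         moments_defined = x$moments_defined)
}

#' Plot a lung density histogram
#'
#' @param object A `density_histogram` from [compute_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_histogram <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_width"), fill = "grey30") +
    ggplot2::labs(x = "Attenuation (HU)", y = "Voxel count",
                  title = sprintf("Lung density histogram (%s)",
                                  attr(object, "region"))) +
    ggplot2::theme_minimal()
}
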