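#' Threshold specifications for CT-density scoring
#'
#' A threshold rule is either *fixed* (an absolute HU value) or *adapted*
#' (defined relative to the patient's own density histogram as
#' `base + offset + k * SD`, base = MLD or Mode). Adapted thresholds
#' compensate for global density shifts due to the inspiration level: an
#' affine change of all lung HU moves MLD, Mode and SD with it, so the
#' resulting score is unchanged, while fixed-threshold scores drift.
#'
#' @param value Fixed threshold in HU.
#' @param base `"MLD"` or `"Mode"` — histogram feature the threshold is
#'   anchored to.
#' @param offset Additive offset in HU (default 0).
#' @param k Multiplier of the region SD (default 0). An adapted spec must
#'   use at least one of `offset`, `k`.
#' @param name Optional display name; a conventional one (e.g.
#'   `"MLD+1SD"`, `"Mode+300"`) is derived when omitted.
#' @return A `threshold_spec` list with fields `name`, `kind`, and either
#'   `value` or `base`/`offset`/`k`.
#' @seealso [default_threshold_suite()], [resolve_threshold()]
#' @export
#' @examples
#' threshold_fixed(-500)
#' threshold_adapted("MLD", k = 1)
#' threshold_adapted("Mode", offset = 300)
threshold_fixed <- function(value, name = NULL) {
  if (!is.finite(value)) {
    abort("Fixed threshold must be a finite HU value.",
          class = "lungdens_validation_error")
  }
  structure(list(name = name %||% sprintf("fixed_%+d", as.integer(round(value))),
                 kind = "fixed", value = as.numeric(value)),
            class = "threshold_spec")
}

#' @rdname threshold_fixed
#' @export
threshold_adapted <- function(base = c("MLD", "Mode"), offset = 0, k = 0,
                              name = NULL) {
  base <- match.arg(base)
  if (!is.finite(offset) || !is.finite(k)) {
    abort("`offset` and `k` must be finite.",
          class = "lungdens_validation_error")
  }
  if (offset == 0 && k == 0) {
    abort("An adapted threshold needs a non-zero `offset` or `k` (or both).",
          class = "lungdens_validation_error")
  }
  if (is.null(name)) {
    parts <- character(0)
    if (k != 0) parts <- c(parts, sprintf("%+gSD", k))
    if (offset != 0) parts <- c(parts, sprintf("%+g", offset))
    name <- paste0(base, paste(parts, collapse = ""))
    name <- sub("\\+", "+", name)
  }
  structure(list(name = name, kind = "adapted", base = base,
                 offset = as.numeric(offset), k = as.numeric(k)),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  if (x$kind == "fixed") {
    cat(sprintf("<threshold_spec> %s: fixed %g HU\n", x$name, x$value))
  } else {
    cat(sprintf("<threshold_spec> %s: %s %+g HU %+g*SD\n", x$name, x$base,
                x$offset, x$k))
  }
  invisible(x)
}

#' The default threshold suite
#'
#' Twelve thresholds evaluated per scan: four fixed values
#' (-300, -400, -500, -600 HU) and eight histogram-adapted rules
#' (MLD+2SD, MLD+1SD, Mode+500, Mode+400, Mode+300, Mode+3SD, Mode+2SD,
#' Mode+1SD). `MLD+1SD` is marked `recommended`: among the suite it is the
#' adapted threshold with the strongest observed association with
#' spirometric impairment, and it only needs the two quantities every
#' densitometry tool reports (MLD and SD).
#'
#' @return A named list of [threshold_fixed()]/[threshold_adapted()] specs;
#'   the recommended member carries attribute `recommended = TRUE`.
#' @export
default_threshold_suite <- function() {
  specs <- list(
    threshold_fixed(-300), threshold_fixed(-400),
    threshold_fixed(-500), threshold_fixed(-600),
    threshold_adapted("MLD", k = 2), threshold_adapted("MLD", k = 1),
    threshold_adapted("Mode", offset = 500),
    threshold_adapted("Mode", offset = 400),
    threshold_adapted("Mode", offset = 300),
    threshold_adapted("Mode", k = 3), threshold_adapted("Mode", k = 2),
    threshold_adapted("Mode", k = 1))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  attr(specs[["MLD+1SD"]], "recommended") <- TRUE
  specs
}

#' Resolve a threshold rule against histogram features
#'
#' @param spec A [threshold_fixed()] or [threshold_adapted()] spec.
#' @param feats A `hist_features` object from [compute_features()]
#'   (ignored for fixed specs).
#' @return The threshold in HU.
#' @export
resolve_threshold <- function(spec, feats = NULL) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (spec$kind == "fixed") return(spec$value)
  if (is.null(feats) || !inherits(feats, "hist_features")) {
    abort("Adapted thresholds need `feats` (hist_features).",
          class = "lungdens_validation_error")
  }
  if (spec$k != 0 && (!is.finite(feats$sd) || feats$sd <= 0)) {
    abort(sprintf("Cannot resolve %s: region SD is zero/undefined.", spec$name),
          class = "lungdens_validation_error")
  }
  base_val <- switch(spec$base, MLD = feats$mld, Mode = feats$mode)
  if (!is.finite(base_val)) {
    abort(sprintf("Cannot resolve %s: %s undefined.", spec$name, spec$base),
          class = "lungdens_validation_error")
  }
  base_val + spec$offset + spec$k * feats$sd
}

#' CT-density score of a region
#'
#' The CT-density score is the percentage of region voxels with
#' attenuation at or above the threshold (the comparison is inclusive: a
#' voxel exactly at the threshold counts). A score of 10 means 10% of the
#' lung is at least as dense as the threshold.
#'
#' @param vol A [ct_volume()].
#' @param mask A [lung_mask()] on the same grid.
#' @param region Region selector.
#' @param threshold Threshold in HU (already resolved).
#' @param spec_name Optional label for the output row.
#' @return One-row tibble: `region`, `spec`, `threshold_hu`, `score`
#'   (percent, 0-100), `n_voxels`.
#' @export
compute_score <- function(vol, mask, region = "whole", threshold,
                          spec_name = NA_character_) {
  v <- masked_values(vol, mask, region)
  if (length(v) == 0L) {
    abort(sprintf("Region '%s' is empty.", region),
          class = "lungdens_region_error")
  }
  tibble(region = region, spec = spec_name,
         threshold_hu = as.numeric(threshold),
         score = 100 * sum(v >= threshold) / length(v),
         n_voxels = length(v))
}

#' Score a region under a suite of thresholds
#'
#' Resolves every spec against the region's histogram features and scores
#' the region under each resolved threshold.
#'
#' @inheritParams compute_score
#' @param specs List of threshold specs; default [default_threshold_suite()].
#' @param feats Optional precomputed `hist_features` for the region.
#' @return Tibble with one row per spec: `region`, `spec`, `kind`,
#'   `threshold_hu`, `score`, `n_voxels`, `recommended`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(48, 48, 48), seed = 7))
#' score_suite(ph$volume, ph$mask)
score_suite <- function(vol, mask, specs = default_threshold_suite(),
                        region = "whole", feats = NULL) {
  if (length(specs) == 0L) {
    abort("`specs` must contain at least one threshold spec.",
          class = "lungdens_validation_error")
  }
  if (inherits(specs, "threshold_spec")) specs <- list(specs)
  feats <- feats %||% compute_features(vol, mask, region)
  purrr::map_dfr(specs, function(sp) {
    thr <- resolve_threshold(sp, feats)
    compute_score(vol, mask, region, thr, spec_name = sp$name) %>%
      mutate(kind = sp$kind,
             recommended = isTRUE(attr(sp, "recommended")),
             .after = "spec")
  })
}

#' Regional (upper/lower/whole) CT-density scores under one rule
#'
#' Resolves the threshold once from WHOLE-lung features and applies the
#' same resolved threshold to the whole, upper and lower regions, so that
#' upper-vs-lower differences reflect regional disease burden rather than
#' regional histogram shifts. Set `resolve_from = "region"` to resolve
#' adapted thresholds per region instead.
#'
#' @inheritParams compute_score
#' @param spec A single threshold spec; default MLD+1SD.
#' @param resolve_from `"whole"` (default) or `"region"`.
#' @return Tibble with rows `whole`, `upper`, `lower`.
#' @export
regional_scores <- function(vol, mask, spec = threshold_adapted("MLD", k = 1),
                            resolve_from = c("whole", "region")) {
  resolve_from <- match.arg(resolve_from)
  stopifnot(inherits(spec, "threshold_spec"))
  regions <- c("whole", "upper", "lower")
  feats_whole <- compute_features(vol, mask, "whole")
  purrr::map_dfr(regions, function(reg) {
    feats <- if (resolve_from == "whole") feats_whole
             else compute_features(vol, mask, reg)
    thr <- resolve_threshold(spec, feats)
    compute_score(vol, mask, reg, thr, spec_name = spec$name)
  })
}
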