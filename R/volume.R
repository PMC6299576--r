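#' CT volume in Hounsfield units
#'
#' An in-memory 3-D CT volume. Voxel values are attenuation in Hounsfield
#' units (HU; air ~ -1000, water 0, soft tissue ~ +40). The voxel grid is
#' column-major with the canonical axis convention: axis 1 = left-right,
#' axis 2 = anterior-posterior, axis 3 = craniocaudal with superior at
#' increasing slice index (axial slices along the last axis). Volumes read
#' from NIfTI are reoriented to this convention on load.
#'
#' @param voxels 3-D numeric array of HU values.
#' @param spacing Numeric length-3, voxel spacing `(dx, dy, dz)` in mm;
#'   strictly positive.
#' @param origin Numeric length-3, physical (world) coordinates of the first
#'   voxel in mm.
#' @param axes Character tag recording the axis convention; `"RAS"` is the
#'   canonical in-memory orientation.
#'
#' @details HU values below -1024 are physically implausible on most
#'   scanners; they are retained (no clipping) but the object carries a
#'   `n_below_floor` attribute and construction emits a message so the
#'   anomaly is visible. Non-finite voxels are rejected.
#'
#' @return An object of class `ct_volume`.
#' @seealso [read_volume()], [write_volume()], [lung_mask()]
#' @export
#' @examples
#' vol <- ct_volume(array(-850, c(4, 4, 4)), spacing = c(1, 1, 1))
#' vol
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      axes = "RAS") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3-D array.", class = "lungdens_validation_error")
  }
  if (length(voxels) == 0L) {
    abort("CT volume has 0 voxels.", class = "lungdens_validation_error")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 strictly positive finite values (mm).",
          class = "lungdens_validation_error")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    abort("`origin` must be 3 finite values (mm).",
          class = "lungdens_validation_error")
  }
  storage.mode(voxels) <- "double"
  if (anyNA(voxels) || any(!is.finite(voxels))) {
    abort("CT volume contains non-finite HU values.",
          class = "lungdens_validation_error")
  }
  n_low <- sum(voxels < -1024)
  if (n_low > 0) {
    message(sprintf("ct_volume: %d voxel(s) below -1024 HU retained unclipped.",
                    n_low))
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin, axes = axes),
    n_below_floor = n_low,
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm (%s)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$axes))
  cat(sprintf("  HU range [%.1f, %.1f], mean %.1f\n",
              min(x$voxels), max(x$voxels), mean(x$voxels)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Voxel volume in millilitres
#'
#' @param x A [ct_volume()] or [lung_mask()].
#' @return Volume of one voxel in mL.
#' @export
voxel_volume_ml <- function(x) prod(x$spacing) / 1000

#' Labeled lung mask bound to a CT volume grid
#'
#' A voxel label map on the same grid as its CT volume: 0 = outside the
#' lungs, positive integers are named lung regions. A freshly segmented
#' mask uses `c(right = 1, left = 2)`; after [split_upper_lower()] the
#' regions are `right_upper`, `right_lower`, `left_upper`, `left_lower`.
#' Region selectors used throughout the package resolve against the region
#' names: `"whole"` (every positive label), `"upper"` / `"lower"` (names
#' with that suffix), `"right"` / `"left"` (names with that prefix), or an
#' exact region name.
#'
#' @param labels 3-D integer array (0 = background).
#' @param region_map Named integer vector mapping region name -> label.
#' @param spacing Voxel spacing in mm, as in [ct_volume()].
#' @param origin Grid origin in mm.
#' @return An object of class `lung_mask`.
#' @export
#' @examples
#' lab <- array(0L, c(4, 4, 4)); lab[2:3, 2:3, ] <- 1L
#' lung_mask(lab, c(lung = 1))
lung_mask <- function(labels, region_map, spacing = c(1, 1, 1),
                      origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    abort("`labels` must be a 3-D array.", class = "lungdens_validation_error")
  }
  if (any(labels != round(labels), na.rm = TRUE)) {
    abort("Mask labels must be integers.", class = "lungdens_validation_error")
  }
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L)) {
    abort("Mask labels must be non-negative integers without NA.",
          class = "lungdens_validation_error")
  }
  region_map <- vapply(region_map, as.integer, integer(1))
  if (is.null(names(region_map)) || any(!nzchar(names(region_map)))) {
    abort("`region_map` must be a named integer vector.",
          class = "lungdens_validation_error")
  }
  present <- sort(unique(labels[labels > 0L]))
  unknown <- setdiff(present, region_map)
  if (length(unknown)) {
    abort(sprintf("Mask contains labels not in the region map: %s",
                  paste(unknown, collapse = ", ")),
          class = "lungdens_validation_error")
  }
  structure(
    list(labels = labels, region_map = region_map,
         spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "lung_mask"
  )
}

#' @export
print.lung_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<lung_mask> %d x %d x %d, %d labeled voxel(s)\n",
              d[1], d[2], d[3], sum(x$labels > 0L)))
  for (nm in names(x$region_map)) {
    cat(sprintf("  %-12s label %d: %d voxels\n", nm, x$region_map[[nm]],
                sum(x$labels == x$region_map[[nm]])))
  }
  invisible(x)
}

#' @export
dim.lung_mask <- function(x) dim(x$labels)

# Resolve a region selector to the integer labels it covers.
region_labels <- function(mask, region) {
  rm_ <- mask$region_map
  if (identical(region, "whole") || identical(region, "all")) {
    return(unname(rm_))
  }
  if (region %in% names(rm_)) return(unname(rm_[[region]]))
  hit <- switch(region,
    upper = rm_[endsWith(names(rm_), "upper")],
    lower = rm_[endsWith(names(rm_), "lower")],
    right = rm_[startsWith(names(rm_), "right")],
    left  = rm_[startsWith(names(rm_), "left")],
    NULL)
  if (is.null(hit) || length(hit) == 0L) {
    abort(sprintf("Unknown region '%s'; available: %s", region,
                  paste(c("whole", names(rm_)), collapse = ", ")),
          class = "lungdens_region_error")
  }
  unname(hit)
}

# Logical voxel selector for a region; errors if vol grid mismatches.
region_selector <- function(mask, region) {
  mask$labels %in% region_labels(mask, region) & mask$labels > 0L
}

# HU values of a region, with grid-compatibility check.
masked_values <- function(vol, mask, region) {
  check_alignment(vol, mask)
  sel <- region_selector(mask, region)
  vol$voxels[sel]
}

check_alignment <- function(vol, mask, tol = 1e-3) {
  if (!identical(dim(vol$voxels), dim(mask$labels))) {
    abort(sprintf(
      "Mask grid (%s) does not match volume grid (%s).",
      paste(dim(mask$labels), collapse = "x"),
      paste(dim(vol$voxels), collapse = "x")),
      class = "lungdens_alignment_error")
  }
  if (any(abs(vol$spacing - mask$spacing) > tol)) {
    abort(sprintf(
      "Mask spacing (%s mm) does not match volume spacing (%s mm).",
      paste(signif(mask$spacing, 6), collapse = ", "),
      paste(signif(vol$spacing, 6), collapse = ", ")),
      class = "lungdens_alignment_error")
  }
  invisible(TRUE)
}
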