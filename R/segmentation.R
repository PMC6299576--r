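#' Segmentation parameters
#'
#' Parameters of the rule-based lung extraction. Lung parenchyma at full
#' inspiration sits near -850 HU, far below mediastinal soft tissue
#' (~ +40 HU), so a single air threshold separates lung-candidate air from
#' the body; the remaining steps clean up vessels, lesions and airways.
#'
#' @param air_threshold HU cut below which a voxel is lung-candidate air;
#'   must lie in (-1000, 0). Default -320 HU.
#' @param closing_radius_mm Radius (mm) of the ball structuring element for
#'   the final morphological closing; 0 disables closing.
#' @param min_volume_ml Minimum connected-component volume (mL) for a
#'   candidate to count as a lung. Default 200 mL.
#' @param remove_trachea Remove narrow cranial midline air columns
#'   (trachea / main bronchi) before selecting lung components.
#' @param trachea_area_mm2 Maximum mean per-slice cross-section (mm^2) for a
#'   component to qualify as airway.
#' @return A `seg_params` list.
#' @export
seg_params <- function(air_threshold = -320, closing_radius_mm = 2,
                       min_volume_ml = 200, remove_trachea = TRUE,
                       trachea_area_mm2 = 300) {
  if (!is.finite(air_threshold) || air_threshold <= -1000 || air_threshold >= 0) {
    abort("`air_threshold` must lie in (-1000, 0) HU.",
          class = "lungdens_validation_error")
  }
  if (closing_radius_mm < 0) {
    abort("`closing_radius_mm` must be >= 0.",
          class = "lungdens_validation_error")
  }
  if (min_volume_ml <= 0) {
    abort("`min_volume_ml` must be > 0.", class = "lungdens_validation_error")
  }
  structure(list(air_threshold = air_threshold,
                 closing_radius_mm = closing_radius_mm,
                 min_volume_ml = min_volume_ml,
                 remove_trachea = isTRUE(remove_trachea),
                 trachea_area_mm2 = trachea_area_mm2),
            class = "seg_params")
}

ball_offsets <- function(radius_mm, spacing) {
  r_vox <- pmax(0L, as.integer(floor(radius_mm / spacing)))
  g <- expand.grid(dx = -r_vox[1]:r_vox[1], dy = -r_vox[2]:r_vox[2],
                   dz = -r_vox[3]:r_vox[3])
  d2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2
  m <- as.matrix(g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

# Components touching any face of the volume (outside air, cropped anatomy,
# airway columns reaching the top of the stack).
border_components <- function(lab, dims) {
  unique(c(lab[c(1, dims[1]), , ], lab[, c(1, dims[2]), ],
           lab[, , c(1, dims[3])]))
}

#' Segment the lungs from a chest CT
#'
#' Rule-based lung extraction: threshold at `air_threshold` -> 3-D
#' connected components -> discard components touching the volume border
#' (outside air) -> optionally remove narrow cranial airway columns ->
#' keep up to two components at least `min_volume_ml` -> per-slice hole
#' filling (recovers vessels and dense lesions inside the lung) ->
#' morphological closing. The result is labeled `right` / `left` by
#' component centroid along the first (left-right) axis; a fused single
#' component is split at the midsagittal plane of the body bounding box.
#'
#' @param vol A [ct_volume()] covering the whole thorax.
#' @param params A [seg_params()] list.
#' @return A [lung_mask()] with regions `c(right = 1, left = 2)`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(64, 64, 64), seed = 1))
#' m <- segment_lungs(ph$volume)
#' m
segment_lungs <- function(vol, params = seg_params()) {
  stopifnot(inherits(vol, "ct_volume"))
  dims <- dim(vol$voxels)
  vv_ml <- voxel_volume_ml(vol)

  if (!any(vol$voxels > -200)) {
    abort("No body detected: no voxels above -200 HU.",
          class = "lungdens_segmentation_error")
  }

  air <- vol$voxels < params$air_threshold
  lab <- array(.cc_label_3d(as.logical(air), dims), dims)

  drop <- setdiff(border_components(lab, dims), 0L)
  tab <- tabulate(lab[lab > 0L])
  candidates <- setdiff(which(tab > 0), drop)

  if (params$remove_trachea && length(candidates)) {
    airway <- vapply(candidates, function(k) {
      is_airway_component(lab, k, dims, vol$spacing, params$trachea_area_mm2)
    }, logical(1))
    candidates <- candidates[!airway]
  }

  vols_ml <- tab[candidates] * vv_ml
  candidates <- candidates[vols_ml >= params$min_volume_ml]
  if (length(candidates) == 0L) {
    abort(sprintf("No lung found: no air component of at least %g mL inside the body.",
                  params$min_volume_ml),
          class = "lungdens_segmentation_error")
  }
  candidates <- candidates[order(tab[candidates], decreasing = TRUE)]
  candidates <- head(candidates, 2L)

  lungs <- array(lab %in% candidates, dims)
  lungs <- array(.fill_holes_slicewise(as.logical(lungs), dims), dims)
  if (params$closing_radius_mm > 0) {
    off <- ball_offsets(params$closing_radius_mm, vol$spacing)
    if (nrow(off) > 1L) {
      lungs <- array(.binary_dilate_3d(as.logical(lungs), dims, off), dims)
      lungs <- array(.binary_erode_3d(as.logical(lungs), dims, off), dims)
    }
  }

  lab2 <- array(.cc_label_3d(as.logical(lungs), dims), dims)
  ncomp <- max(lab2)
  labels <- array(0L, dims)
  if (ncomp >= 2L) {
    # two largest are the lungs (labels sorted by size already)
    cx <- vapply(1:2, function(k) mean(which(lab2 == k, arr.ind = TRUE)[, 1]),
                 numeric(1))
    right_first <- cx[1] < cx[2]  # canonical RAS: +x is patient left
    labels[lab2 == (if (right_first) 1L else 2L)] <- 1L
    labels[lab2 == (if (right_first) 2L else 1L)] <- 2L
    if (ncomp > 2L) labels[lab2 > 2L] <- 0L
  } else {
    # fused lungs: split at the midsagittal plane of the body bounding box
    body <- which(vol$voxels > -200, arr.ind = TRUE)
    mid <- (min(body[, 1]) + max(body[, 1])) / 2
    idx <- which(lab2 == 1L, arr.ind = TRUE)
    flat <- which(lab2 == 1L)
    labels[flat[idx[, 1] <= mid]] <- 1L
    labels[flat[idx[, 1] > mid]] <- 2L
  }

  lung_mask(labels, region_map = c(right = 1L, left = 2L),
            spacing = vol$spacing, origin = vol$origin)
}

# Airway heuristic: small mean per-slice cross-section, centroid near the
# midsagittal plane, present in the cranial third of the stack.
is_airway_component <- function(lab, k, dims, spacing, max_area_mm2) {
  idx <- which(lab == k, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(FALSE)
  nsl <- length(unique(idx[, 3]))
  area_mm2 <- nrow(idx) / nsl * spacing[1] * spacing[2]
  cranial <- max(idx[, 3]) >= dims[3] * 2 / 3
  central <- abs(mean(idx[, 1]) - (dims[1] + 1) / 2) < dims[1] * 0.15
  area_mm2 <= max_area_mm2 && cranial && central
}

#' Split a lung mask into upper and lower regions
#'
#' The comparison of disease burden between upper and lower lungs needs a
#' craniocaudal partition. Two methods are supported: `axial_fraction`
#' places a given fraction of each lung's voxels cranially (default 0.5, a
#' volume-halving plane per lung), and `lobe_labels` groups a supplied lobe
#' label map into upper = \{right upper lobe, upper part of the left upper
#' lobe\} and lower = \{middle lobe, lingula, lower lobes\}.
#'
#' @param mask A [lung_mask()] with `right`/`left` regions.
#' @param method `"axial_fraction"` or `"lobe_labels"`.
#' @param fraction For `axial_fraction`: fraction of each lung's voxels
#'   assigned to the upper region, in (0, 1).
#' @param lobe_map For `lobe_labels`: a [lung_mask()] whose region names
#'   include `RUL`, `RML`, `RLL`, `LUL_upper`, `lingula`, `LLL`.
#' @return A [lung_mask()] with regions `right_upper`, `right_lower`,
#'   `left_upper`, `left_lower`.
#' @export
split_upper_lower <- function(mask, method = c("axial_fraction", "lobe_labels"),
                              fraction = 0.5, lobe_map = NULL) {
  stopifnot(inherits(mask, "lung_mask"))
  method <- match.arg(method)
  if (sum(mask$labels > 0L) == 0L) {
    abort("Empty lung mask: nothing to split.",
          class = "lungdens_segmentation_error")
  }
  out_map <- c(right_upper = 1L, right_lower = 2L,
               left_upper = 3L, left_lower = 4L)
  labels <- array(0L, dim(mask$labels))

  if (method == "axial_fraction") {
    if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
      abort("`fraction` must lie strictly inside (0, 1).",
            class = "lungdens_validation_error")
    }
    sides <- list(right = region_labels(mask, "right"),
                  left = region_labels(mask, "left"))
    for (side in names(sides)) {
      sel <- mask$labels %in% sides[[side]] & mask$labels > 0L
      if (!any(sel)) next
      zs <- slice_index(dim(mask$labels))[sel]
      counts <- tabulate(zs, nbins = dim(mask$labels)[3])
      # smallest upper block (from the top) holding >= fraction of voxels
      from_top <- rev(cumsum(rev(counts)))
      z_cut <- max(which(from_top >= fraction * sum(counts)))
      up <- sel & slice_index(dim(mask$labels)) >= z_cut
      lo <- sel & !up
      labels[up] <- out_map[[paste0(side, "_upper")]]
      labels[lo] <- out_map[[paste0(side, "_lower")]]
    }
  } else {
    if (is.null(lobe_map) || !inherits(lobe_map, "lung_mask")) {
      abort("`lobe_labels` requires `lobe_map`, a lung_mask of lobe labels.",
            class = "lungdens_validation_error")
    }
    grouping <- list(
      right_upper = "RUL", left_upper = "LUL_upper",
      right_lower = c("RML", "RLL"), left_lower = c("lingula", "LLL"))
    missing_l <- setdiff(unlist(grouping), names(lobe_map$region_map))
    if (length(missing_l)) {
      abort(sprintf("Lobe map lacks region(s): %s",
                    paste(missing_l, collapse = ", ")),
            class = "lungdens_validation_error")
    }
    inside <- mask$labels > 0L
    for (reg in names(grouping)) {
      lobes <- unname(lobe_map$region_map[grouping[[reg]]])
      labels[inside & lobe_map$labels %in% lobes] <- out_map[[reg]]
    }
  }

  lung_mask(labels, region_map = out_map, spacing = mask$spacing,
            origin = mask$origin)
}

slice_index <- function(dims) {
  array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dims)
}

#' Volume of a mask region in millilitres
#'
#' @param mask A [lung_mask()].
#' @param region Region selector (see [lung_mask()]); default `"whole"`.
#' @return Volume in mL (voxel count times voxel volume).
#' @export
mask_volume_ml <- function(mask, region = "whole") {
  stopifnot(inherits(mask, "lung_mask"))
  sum(region_selector(mask, region)) * voxel_volume_ml(mask)
}
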