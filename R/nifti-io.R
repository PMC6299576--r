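#' Read a CT volume from NIfTI or a DICOM series
#'
#' Loads a chest CT as a HU-calibrated [ct_volume()]. NIfTI volumes are
#' reoriented to the canonical RAS convention (axial slices along the last
#' axis, superior at increasing index). DICOM series are rescaled to HU via
#' the RescaleSlope/RescaleIntercept tags and slices are sorted by physical
#' position along the table axis.
#'
#' @param path Path to a `.nii`/`.nii.gz` file or to a directory holding
#'   one DICOM series.
#' @param format One of `"auto"` (directory implies DICOM), `"nifti"`,
#'   `"dicom_dir"`.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_dir")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("Input path does not exist: %s", path),
          class = "lungdens_io_error")
  }
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_dir" else "nifti"
  }
  if (format == "dicom_dir") {
    return(read_dicom_series(path))
  }
  img <- RNifti::readNifti(path)
  if (!identical(RNifti::orientation(img), "RAS")) {
    RNifti::orientation(img) <- "RAS"
  }
  vox <- as.array(img)
  if (length(dim(vox)) == 4L && dim(vox)[4] == 1L) {
    vox <- array(vox, dim(vox)[1:3])
  }
  if (length(dim(vox)) != 3L) {
    abort(sprintf("Expected a 3-D volume, got %d dimensions.",
                  length(dim(vox))), class = "lungdens_io_error")
  }
  vox <- array(as.double(vox), dim(vox))  # drop niftiImage attributes
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- tryCatch(as.numeric(RNifti::voxelToWorld(c(1, 1, 1), img)),
                     error = function(e) c(0, 0, 0))
  ct_volume(vox, spacing = spacing, origin = origin, axes = "RAS")
}

#' Write a CT volume to NIfTI
#'
#' Stores voxels as float64 so that a write/read round trip is lossless
#' for values and spacing.
#'
#' @param vol A [ct_volume()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!dir.exists(dirname(path))) {
    abort(sprintf("Directory is not writable or missing: %s", dirname(path)),
          class = "lungdens_io_error")
  }
  img <- nifti_with_geometry(vol$voxels, vol$spacing, vol$origin)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

nifti_with_geometry <- function(arr, spacing, origin, datatype = "double") {
  arr <- unclass(arr)
  attr(arr, "pixdim") <- spacing  # qform scaling comes from the pixdim field
  img <- RNifti::asNifti(arr, datatype = datatype)
  aff <- rbind(cbind(diag(spacing), as.numeric(origin)), c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 1L)
  img
}

#' Read a lung/lobe label mask bound to a volume
#'
#' Reads a NIfTI label map and binds it to `vol` after checking grid
#' alignment (same shape; spacing equal within 1e-3 mm). Region names are
#' taken from a JSON sidecar (`<mask>.json`, a `{"name": label}` object)
#' when present, otherwise labels are named `region_<k>`.
#'
#' @param path NIfTI label-map path.
#' @param vol The [ct_volume()] the mask belongs to.
#' @return A [lung_mask()].
#' @export
read_mask <- function(path, vol) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!file.exists(path)) {
    abort(sprintf("Mask path does not exist: %s", path),
          class = "lungdens_io_error")
  }
  img <- RNifti::readNifti(path)
  if (!identical(RNifti::orientation(img), "RAS")) {
    RNifti::orientation(img) <- "RAS"
  }
  lab <- as.array(img)
  if (length(dim(lab)) == 4L && dim(lab)[4] == 1L) lab <- array(lab, dim(lab)[1:3])
  if (any(lab != round(lab))) {
    abort("Mask file contains non-integer label values.",
          class = "lungdens_validation_error")
  }
  spacing <- RNifti::pixdim(img)[1:3]
  sidecar <- sidecar_path(path)
  region_map <- if (file.exists(sidecar)) {
    rm_ <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    vapply(rm_, as.integer, integer(1))
  } else {
    labs <- sort(unique(lab[lab > 0]))
    stats::setNames(as.integer(labs), paste0("region_", labs))
  }
  mask <- lung_mask(array(as.integer(round(lab)), dim(lab)),
                    region_map = region_map,
                    spacing = spacing, origin = vol$origin)
  check_alignment(vol, mask)
  mask
}

#' Write a lung mask as a NIfTI label map plus JSON sidecar
#'
#' @param mask A [lung_mask()].
#' @param path Output `.nii`/`.nii.gz` path; the region map is written to a
#'   `.json` sidecar next to it.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lung_mask"))
  img <- nifti_with_geometry(mask$labels, mask$spacing, mask$origin,
                             datatype = "uint16")
  RNifti::writeNifti(img, path, datatype = "uint16")
  jsonlite::write_json(as.list(mask$region_map), sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".json")
}
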