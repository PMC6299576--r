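# Minimal explicit-VR little-endian DICOM writer, used only to build
# test fixtures on the fly (binary files are never shipped).

dcm_element <- function(group, elem, vr, payload) {
  tag <- writeBin(c(as.integer(group), as.integer(elem)), raw(),
                  size = 2L, endian = "little")
  if (vr %in% c("OB", "OW", "SQ", "UT", "UN")) {
    len <- writeBin(as.integer(length(payload)), raw(), size = 4L,
                    endian = "little")
    c(tag, charToRaw(vr), as.raw(c(0, 0)), len, payload)
  } else {
    len <- writeBin(as.integer(length(payload)), raw(), size = 2L,
                    endian = "little")
    c(tag, charToRaw(vr), len, payload)
  }
}

dcm_str <- function(s, null_pad = FALSE) {
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L) r <- c(r, if (null_pad) as.raw(0) else charToRaw(" "))
  r
}

dcm_us <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                               endian = "little")

# Write one slice; `omit` drops tags by name to provoke errors.
write_dicom_slice <- function(path, pixels, z, spacing = c(1, 1, 1),
                              slope = 1, intercept = -1024,
                              series_uid = "1.2.826.0.1.999999.1",
                              omit = character(0)) {
  stored <- round((pixels - intercept) / slope)
  stopifnot(all(stored >= 0 & stored <= 65535))
  # pixels arrive [x, y]; DICOM stores row-major (y rows of x columns)
  px_raw <- writeBin(as.integer(stored), raw(), size = 2L, endian = "little")

  body <- c(
    dcm_element(0x0008, 0x0016, "UI", dcm_str("1.2.840.10008.5.1.4.1.1.2", TRUE)),
    dcm_element(0x0008, 0x0018, "UI",
                dcm_str(paste0(series_uid, ".", z), TRUE)),
    if (!"series_uid" %in% omit)
      dcm_element(0x0020, 0x000E, "UI", dcm_str(series_uid, TRUE)),
    dcm_element(0x0020, 0x0013, "IS", dcm_str(as.character(z))),
    if (!"ipp" %in% omit)
      dcm_element(0x0020, 0x0032, "DS",
                  dcm_str(sprintf("0\\0\\%g", (z - 1) * spacing[3]))),
    dcm_element(0x0018, 0x0050, "DS", dcm_str(as.character(spacing[3]))),
    dcm_element(0x0028, 0x0010, "US", dcm_us(ncol(pixels))),   # Rows
    dcm_element(0x0028, 0x0011, "US", dcm_us(nrow(pixels))),   # Columns
    dcm_element(0x0028, 0x0030, "DS",
                dcm_str(sprintf("%g\\%g", spacing[2], spacing[1]))),
    dcm_element(0x0028, 0x0100, "US", dcm_us(16)),
    dcm_element(0x0028, 0x0103, "US", dcm_us(0)),
    if (!"intercept" %in% omit)
      dcm_element(0x0028, 0x1052, "DS", dcm_str(as.character(intercept))),
    if (!"slope" %in% omit)
      dcm_element(0x0028, 0x1053, "DS", dcm_str(as.character(slope))),
    dcm_element(0x7FE0, 0x0010, "OW", px_raw))

  meta <- dcm_element(0x0002, 0x0010, "UI",
                      dcm_str("1.2.840.10008.1.2.1", TRUE))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# Write a whole series (one file per slice) from a 3-D HU array.
write_dicom_series <- function(dir, voxels, spacing = c(1, 1, 1),
                               slope = 1, intercept = -1024,
                               series_uid = "1.2.826.0.1.999999.1",
                               omit = character(0), shuffle = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- dim(voxels)[3]
  order_z <- if (shuffle) rev(seq_len(nz)) else seq_len(nz)
  for (z in order_z) {
    write_dicom_slice(file.path(dir, sprintf("slice_%03d.dcm", z)),
                      voxels[, , z], z = z, spacing = spacing,
                      slope = slope, intercept = intercept,
                      series_uid = series_uid, omit = omit)
  }
  invisible(dir)
}
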