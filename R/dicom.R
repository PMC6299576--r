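# Minimal DICOM series reader: part-10 files, implicit/explicit VR little
# endian, uncompressed 16-bit pixel data — the subset produced by CT
# scanners for axial reconstructions. Kept deliberately small; anything
# outside this subset raises a typed error rather than guessing.

DICOM_TAGS <- list(
  series_uid   = list(group = 0x0020L, elem = 0x000EL, type = "str"),
  instance     = list(group = 0x0020L, elem = 0x0013L, type = "str"),
  ipp          = list(group = 0x0020L, elem = 0x0032L, type = "str"),
  rows         = list(group = 0x0028L, elem = 0x0010L, type = "u16"),
  cols         = list(group = 0x0028L, elem = 0x0011L, type = "u16"),
  pixel_spacing = list(group = 0x0028L, elem = 0x0030L, type = "str"),
  slice_thickness = list(group = 0x0018L, elem = 0x0050L, type = "str"),
  bits_allocated = list(group = 0x0028L, elem = 0x0100L, type = "u16"),
  pixel_rep    = list(group = 0x0028L, elem = 0x0103L, type = "u16"),
  intercept    = list(group = 0x0028L, elem = 0x1052L, type = "str"),
  slope        = list(group = 0x0028L, elem = 0x1053L, type = "str"),
  pixel_data   = list(group = 0x7FE0L, elem = 0x0010L, type = "raw")
)

LONG_VRS <- c("OB", "OW", "OF", "OL", "OD", "SQ", "UT", "UN", "UC", "UR")

dcm_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
dcm_u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

# Parse one DICOM file, returning the tags in DICOM_TAGS that are present.
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132L || rawToChar(raw[129:132]) != "DICM") {
    abort(sprintf("Not a DICOM part-10 file: %s", path),
          class = "lungdens_io_error")
  }
  pos <- 133L
  explicit <- TRUE
  transfer_syntax <- "1.2.840.10008.1.2.1"
  out <- list()
  in_meta <- TRUE

  while (pos + 7L <= length(raw) + 1L && pos <= length(raw)) {
    group <- dcm_u16(raw, pos)
    elem <- dcm_u16(raw, pos + 2L)
    if (in_meta && group != 0x0002L) {
      # end of file-meta: switch to the negotiated transfer syntax
      in_meta <- FALSE
      explicit <- transfer_syntax != "1.2.840.10008.1.2"
      if (!(transfer_syntax %in%
            c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))) {
        abort(sprintf("Unsupported transfer syntax %s in %s",
                      transfer_syntax, path), class = "lungdens_io_error")
      }
    }
    use_explicit <- in_meta || explicit
    if (use_explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% LONG_VRS) {
        len <- dcm_u32(raw, pos + 8L)
        hdr <- 12L
      } else {
        len <- dcm_u16(raw, pos + 6L)
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- dcm_u32(raw, pos + 4L)
      hdr <- 8L
    }
    if (len >= 4294967295) {
      abort(sprintf("Undefined-length element (%04X,%04X) unsupported in %s",
                    group, elem, path), class = "lungdens_io_error")
    }
    vstart <- pos + hdr
    vend <- vstart + len - 1L
    if (len > 0 && vend > length(raw)) {
      abort(sprintf("Truncated DICOM element (%04X,%04X) in %s",
                    group, elem, path), class = "lungdens_io_error")
    }
    if (in_meta && group == 0x0002L && elem == 0x0010L) {
      transfer_syntax <- dcm_decode_str(raw[vstart:vend])
    }
    for (nm in names(DICOM_TAGS)) {
      tg <- DICOM_TAGS[[nm]]
      if (group == tg$group && elem == tg$elem) {
        val <- raw[seq.int(vstart, length.out = len)]
        out[[nm]] <- switch(tg$type,
          str = dcm_decode_str(val),
          u16 = dcm_u16(val, 1L),
          raw = val)
      }
    }
    pos <- vstart + len
    if (group == 0x7FE0L && elem == 0x0010L) break
  }
  out
}

dcm_decode_str <- function(val) {
  val <- val[val != as.raw(0)]
  sub("\\s+$", "", rawToChar(val))
}

dcm_numeric <- function(str) as.numeric(strsplit(str, "\\\\")[[1]])

decode_pixels <- function(info, path) {
  need <- c("rows", "cols", "bits_allocated", "pixel_data")
  missing_t <- setdiff(need, names(info))
  if (length(missing_t)) {
    abort(sprintf("DICOM file %s lacks required tag(s): %s", path,
                  paste(missing_t, collapse = ", ")),
          class = "lungdens_io_error")
  }
  if (info$bits_allocated != 16L) {
    abort(sprintf("Only 16-bit DICOM pixel data supported (got %d bits) in %s",
                  info$bits_allocated, path), class = "lungdens_io_error")
  }
  signed <- isTRUE(info$pixel_rep == 1L)
  v <- readBin(info$pixel_data, what = "integer", size = 2L,
               n = info$rows * info$cols, signed = signed,
               endian = "little")
  # DICOM pixels are row-major (all columns of the top row first);
  # matrix(v, nrow = cols) yields [x, y] with x = column index
  matrix(v, nrow = info$cols, ncol = info$rows)
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) {
    abort(sprintf("No files in DICOM directory: %s", dir),
          class = "lungdens_io_error")
  }
  slices <- lapply(files, parse_dicom_file)
  uids <- vapply(slices, function(s) s$series_uid %||% NA_character_,
                 character(1))
  if (length(unique(uids[!is.na(uids)])) > 1L) {
    abort(sprintf(
      "Directory mixes %d DICOM series (SeriesInstanceUIDs: %s); supply one acquisition.",
      length(unique(uids)), paste(unique(uids), collapse = "; ")),
      class = "lungdens_mixed_series_error")
  }
  for (i in seq_along(slices)) {
    for (tag in c("slope", "intercept")) {
      if (is.null(slices[[i]][[tag]])) {
        full <- if (tag == "slope") "RescaleSlope (0028,1053)"
                else "RescaleIntercept (0028,1052)"
        abort(sprintf("DICOM file %s is missing the %s tag; cannot calibrate HU.",
                      files[i], full), class = "lungdens_io_error")
      }
    }
  }
  zpos <- vapply(slices, function(s) {
    if (!is.null(s$ipp)) dcm_numeric(s$ipp)[3]
    else if (!is.null(s$instance)) as.numeric(s$instance)
    else NA_real_
  }, numeric(1))
  if (anyNA(zpos)) {
    abort("DICOM slices lack ImagePositionPatient and InstanceNumber; cannot order slices.",
          class = "lungdens_io_error")
  }
  ord <- order(zpos)
  slices <- slices[ord]
  files <- files[ord]
  zpos <- zpos[ord]

  planes <- lapply(seq_along(slices), function(i) {
    px <- decode_pixels(slices[[i]], files[i])
    dcm_numeric(slices[[i]]$slope) * px + dcm_numeric(slices[[i]]$intercept)
  })
  dims <- vapply(planes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("DICOM slices have inconsistent matrix sizes.",
          class = "lungdens_io_error")
  }
  vox <- array(unlist(planes, use.names = FALSE),
               c(dims[1, 1], dims[2, 1], length(planes)))

  ps <- if (!is.null(slices[[1]]$pixel_spacing)) {
    dcm_numeric(slices[[1]]$pixel_spacing)  # (row spacing = dy, col spacing = dx)
  } else c(1, 1)
  dz <- if (length(zpos) > 1L) median(diff(zpos))
        else if (!is.null(slices[[1]]$slice_thickness))
          dcm_numeric(slices[[1]]$slice_thickness)
        else 1
  origin <- if (!is.null(slices[[1]]$ipp)) dcm_numeric(slices[[1]]$ipp)
            else c(0, 0, 0)
  ct_volume(vox, spacing = c(ps[2], ps[1], abs(dz)), origin = origin,
            axes = "RAS")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
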