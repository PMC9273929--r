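# Minimal DICOM support for axial CT series.
#
# Scope: single-frame, single-series axial CT stored with the Explicit VR
# Little Endian transfer syntax (1.2.840.10008.1.2.1), 16-bit pixels.
# Anything else (compressed syntaxes, sequences with undefined length,
# oblique acquisitions) is rejected with a clear error instead of being
# guessed at: this reader exists to ingest screening CT exports and the
# package's own synthetic fixtures, not to be a general DICOM toolkit.

TAGS <- list(
  transfer_syntax  = c(0x0002L, 0x0010L),
  modality         = c(0x0008L, 0x0060L),
  model            = c(0x0008L, 0x1090L),
  patient_id       = c(0x0010L, 0x0020L),
  slice_thickness  = c(0x0018L, 0x0050L),
  kvp              = c(0x0018L, 0x0060L),
  tube_current     = c(0x0018L, 0x1151L),
  series_uid       = c(0x0020L, 0x000EL),
  image_position   = c(0x0020L, 0x0032L),
  image_orientation= c(0x0020L, 0x0037L),
  rows             = c(0x0028L, 0x0010L),
  cols             = c(0x0028L, 0x0011L),
  pixel_spacing    = c(0x0028L, 0x0030L),
  bits_allocated   = c(0x0028L, 0x0100L),
  pixel_repr       = c(0x0028L, 0x0103L),
  rescale_intercept= c(0x0028L, 0x1052L),
  rescale_slope    = c(0x0028L, 0x1053L),
  pixel_data       = c(0x7FE0L, 0x0010L)
)

uint16_at <- function(raw, pos) {
  readBin(raw[pos:(pos + 1)], "integer", size = 2, signed = FALSE, endian = "little")
}
uint32_at <- function(raw, pos) {
  lo <- uint16_at(raw, pos); hi <- uint16_at(raw, pos + 2)
  hi * 65536 + lo
}

# Parse one explicit-VR little-endian file into the elements named in TAGS.
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    abort(paste0("not a DICOM part-10 file: ", path))
  }
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  pos <- 133L
  out <- list()
  while (pos + 7 <= length(raw)) {
    group <- uint16_at(raw, pos)
    elem <- uint16_at(raw, pos + 2)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% long_vrs) {
      len <- uint32_at(raw, pos + 8)
      vstart <- pos + 12L
    } else {
      len <- uint16_at(raw, pos + 6)
      vstart <- pos + 8L
    }
    if (vr == "SQ" || len >= 4294967294) {
      abort(paste0("unsupported DICOM structure (sequence/undefined length) in ", path))
    }
    for (nm in names(TAGS)) {
      tg <- TAGS[[nm]]
      if (group == tg[1] && elem == tg[2]) {
        bytes <- if (len > 0) raw[vstart:(vstart + len - 1)] else raw(0)
        out[[nm]] <- list(vr = vr, bytes = bytes)
      }
    }
    pos <- vstart + len
  }
  out
}

dcm_string <- function(el) {
  if (is.null(el)) return(NULL)
  s <- rawToChar(el$bytes[el$bytes != as.raw(0)])
  trimws(s)
}
dcm_numbers <- function(el) {
  if (is.null(el)) return(NULL)
  as.numeric(strsplit(dcm_string(el), "\\\\")[[1]])
}
dcm_uint16 <- function(el) uint16_at(el$bytes, 1)

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) abort(paste0("ambiguous input: no files in ", dir))
  parsed <- lapply(files, parse_dicom_file)

  ts <- unique(unlist(lapply(parsed, function(p) dcm_string(p$transfer_syntax))))
  if (length(ts) > 0 && any(ts != "1.2.840.10008.1.2.1")) {
    abort("unsupported transfer syntax (only Explicit VR Little Endian is read)")
  }
  modality <- unique(unlist(lapply(parsed, function(p) dcm_string(p$modality))))
  if (!identical(modality, "CT")) {
    abort(paste0("wrong modality: expected CT, found ",
                 paste(modality, collapse = ", ")))
  }
  uids <- unique(unlist(lapply(parsed, function(p) dcm_string(p$series_uid))))
  if (length(uids) != 1) {
    abort("ambiguous input: directory holds more than one DICOM series")
  }

  first <- parsed[[1]]
  orient <- dcm_numbers(first$image_orientation)
  if (!is.null(orient) &&
      max(abs(orient - c(1, 0, 0, 0, 1, 0))) > 1e-3) {
    abort("oblique acquisition not supported (axial orthogonal series only)")
  }

  nr <- dcm_uint16(first$rows)
  nc <- dcm_uint16(first$cols)
  ps <- dcm_numbers(first$pixel_spacing)      # row spacing \ col spacing
  zpos <- vapply(parsed, function(p) {
    ip <- dcm_numbers(p$image_position)
    if (is.null(ip)) abort("DICOM slice lacks ImagePositionPatient")
    ip[3]
  }, numeric(1))
  ord <- order(zpos)
  parsed <- parsed[ord]; zpos <- zpos[ord]

  if (length(zpos) > 1) {
    gaps <- diff(zpos)
    if (any(gaps <= 0)) abort("ambiguous input: duplicate slice positions")
    med <- median(gaps)
    if (any(abs(gaps - med) > 0.1 * med)) {
      abort("irregular geometry: slice spacing varies by more than 10%")
    }
    dz <- med
  } else {
    dz <- dcm_numbers(first$slice_thickness) %||% 1
  }

  slope <- dcm_numbers(first$rescale_slope) %||% 1
  intercept <- dcm_numbers(first$rescale_intercept) %||% 0
  bits <- dcm_uint16(first$bits_allocated)
  if (bits != 16) abort("unsupported DICOM pixel depth (16-bit only)")
  signed <- dcm_uint16(first$pixel_repr) == 1

  vox <- array(0, dim = c(length(parsed), nr, nc))
  for (k in seq_along(parsed)) {
    el <- parsed[[k]]$pixel_data
    if (is.null(el)) abort("DICOM slice lacks pixel data")
    v <- readBin(el$bytes, "integer", n = nr * nc, size = 2,
                 signed = signed, endian = "little")
    vox[k, , ] <- t(matrix(v, nrow = nc))     # stored row-major -> [row, col]
  }
  vox <- slope * vox + intercept              # HU normalization, exactly once

  ip1 <- dcm_numbers(first$image_position)
  dev <- device_meta(
    manufacturer_model = dcm_string(first$model) %||% "unknown",
    kVp = dcm_numbers(first$kvp) %||% 120,
    mA = dcm_numbers(first$tube_current) %||% NA_real_,
    slice_thickness_mm = dcm_numbers(first$slice_thickness) %||% dz,
    rescale_slope = slope, rescale_intercept = intercept
  )
  ct_volume(vox, spacing_mm = c(dz, ps[1], ps[2]),
            origin_mm = c(zpos[1], ip1[2], ip1[1]),
            device = dev,
            patient_id = dcm_string(first$patient_id) %||% "anonymous")
}

# --- writer (internal; used to build synthetic DICOM fixtures) --------------

dcm_elem <- function(group, elem, vr, bytes) {
  if (length(bytes) %% 2 == 1) {
    pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
    bytes <- c(bytes, pad)
  }
  head <- c(
    writeBin(as.integer(group), raw(), size = 2, endian = "little"),
    writeBin(as.integer(elem), raw(), size = 2, endian = "little"),
    charToRaw(vr)
  )
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)),
      writeBin(length(bytes), raw(), size = 4, endian = "little"), bytes)
  } else {
    c(head, writeBin(length(bytes), raw(), size = 2, endian = "little"), bytes)
  }
}
dcm_str_elem <- function(group, elem, vr, s) dcm_elem(group, elem, vr, charToRaw(s))
dcm_us_elem <- function(group, elem, v) {
  dcm_elem(group, elem, "US", writeBin(as.integer(v), raw(), size = 2, endian = "little"))
}

# Write a ct_volume as one explicit-VR LE DICOM file per slice. Stored pixel
# values are computed by inverting the requested rescale so that a compliant
# reader recovers the HU exactly.
write_dicom_series <- function(vol, dir, rescale_slope = 1,
                               rescale_intercept = -1024,
                               series_uid = "1.2.826.0.1.3680043.9999.1",
                               modality = "CT") {
  stopifnot(inherits(vol, "ct_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(vol$voxels)
  dev <- vol$device %||% device_meta()
  for (k in seq_len(d[1])) {
    stored <- round((vol$voxels[k, , ] - rescale_intercept) / rescale_slope)
    if (any(stored < -32768 | stored > 32767)) {
      abort("stored pixel values exceed int16 range for the chosen rescale")
    }
    z <- vol$origin_mm[1] + (k - 1) * vol$spacing_mm[1]
    px <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")

    meta_body <- dcm_str_elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
    meta <- c(
      dcm_elem(0x0002, 0x0000, "UL",
               writeBin(length(meta_body), raw(), size = 4, endian = "little")),
      meta_body
    )
    ds <- c(
      dcm_str_elem(0x0008, 0x0060, "CS", modality),
      dcm_str_elem(0x0008, 0x1090, "LO", dev$manufacturer_model),
      dcm_str_elem(0x0010, 0x0020, "LO", vol$patient_id),
      dcm_str_elem(0x0018, 0x0050, "DS", format(vol$spacing_mm[1])),
      dcm_str_elem(0x0018, 0x0060, "DS", format(dev$kVp)),
      dcm_str_elem(0x0018, 0x1151, "IS", format(round(dev$mA))),
      dcm_str_elem(0x0020, 0x000E, "UI", series_uid),
      dcm_str_elem(0x0020, 0x0032, "DS",
                   paste(format(c(vol$origin_mm[3], vol$origin_mm[2], z)),
                         collapse = "\\")),
      dcm_str_elem(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      dcm_us_elem(0x0028, 0x0002, 1),
      dcm_str_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_us_elem(0x0028, 0x0010, d[2]),
      dcm_us_elem(0x0028, 0x0011, d[3]),
      dcm_str_elem(0x0028, 0x0030, "DS",
                   paste(format(vol$spacing_mm[2:3]), collapse = "\\")),
      dcm_us_elem(0x0028, 0x0100, 16),
      dcm_us_elem(0x0028, 0x0101, 16),
      dcm_us_elem(0x0028, 0x0102, 15),
      dcm_us_elem(0x0028, 0x0103, 1),
      dcm_str_elem(0x0028, 0x1052, "DS", format(rescale_intercept)),
      dcm_str_elem(0x0028, 0x1053, "DS", format(rescale_slope)),
      dcm_elem(0x7FE0, 0x0010, "OW", px)
    )
    out <- c(raw(128), charToRaw("DICM"), meta, ds)
    writeBin(out, file.path(dir, sprintf("slice_%04d.dcm", k)))
  }
  invisible(dir)
}
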