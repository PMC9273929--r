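#' Construct a CT volume
#'
#' The imaging container used throughout the package: a 3-D array of
#' Hounsfield units in `(slice, row, column)` order together with voxel
#' spacing, physical origin and acquisition metadata. The axial slice index
#' increases toward the head; rows run anterior to posterior and columns run
#' patient-right to patient-left. Voxel indices are 1-based.
#'
#' Volumes are tagged as HU-normalized exactly once: the DICOM reader applies
#' the rescale slope/intercept when assembling the volume, and re-applying a
#' rescale to an already normalized volume is an error.
#'
#' @param voxels numeric 3-D array of HU, dim = (n_slice, n_row, n_col).
#' @param spacing_mm length-3 positive numeric, (z, y, x) voxel size in mm.
#' @param origin_mm length-3 numeric, physical position of the first voxel.
#' @param device a [device_meta()] record (or NULL).
#' @param patient_id character scalar.
#' @return an object of class `ct_volume`.
#' @export
#' @examples
#' vol <- ct_volume(array(-1000, dim = c(4, 8, 8)), spacing_mm = c(3, 2, 2))
#' dim(vol$voxels)
ct_volume <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0),
                      device = NULL, patient_id = "anonymous") {
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    abort("voxels must be a 3-D array (slice x row x col)")
  }
  if (any(dim(voxels) < 1)) abort("voxel array is empty in at least one dimension")
  if (!all(is.finite(voxels))) abort("voxels contain non-finite HU values")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    abort("spacing_mm must be three positive finite numbers (z, y, x)")
  }
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3 || any(!is.finite(origin_mm))) {
    abort("origin_mm must be three finite numbers")
  }
  if (!is.null(device) && !inherits(device, "device_meta")) {
    abort("device must be created with device_meta()")
  }
  structure(
    list(
      voxels = voxels,
      spacing_mm = spacing_mm,
      origin_mm = origin_mm,
      device = device,
      patient_id = as.character(patient_id),
      hu_normalized = TRUE
    ),
    class = "ct_volume"
  )
}

#' Scanner acquisition metadata
#'
#' @param manufacturer_model scanner model string, e.g. one of the clinical
#'   low-dose protocols in [device_presets()] or `"synthetic:<name>"`.
#' @param kVp tube voltage, kV (> 0).
#' @param mA tube current.
#' @param slice_thickness_mm reconstructed slice thickness (> 0).
#' @param rescale_slope,rescale_intercept affine map from stored pixel values
#'   to HU, as carried in DICOM headers.
#' @return an object of class `device_meta`.
#' @export
device_meta <- function(manufacturer_model = "synthetic:default",
                        kVp = 120, mA = 250, slice_thickness_mm = 3,
                        rescale_slope = 1, rescale_intercept = -1024) {
  if (!is.finite(kVp) || kVp <= 0) abort("kVp must be > 0")
  if (!is.finite(slice_thickness_mm) || slice_thickness_mm <= 0) {
    abort("slice_thickness_mm must be > 0")
  }
  structure(
    list(
      manufacturer_model = as.character(manufacturer_model),
      kVp = as.numeric(kVp),
      mA = as.numeric(mA),
      slice_thickness_mm = as.numeric(slice_thickness_mm),
      rescale_slope = as.numeric(rescale_slope),
      rescale_intercept = as.numeric(rescale_intercept)
    ),
    class = "device_meta"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels (slice x row x col), spacing %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]
  ))
  cat(sprintf("  HU range [%.1f, %.1f], patient %s, device %s\n",
              min(x$voxels), max(x$voxels), x$patient_id,
              if (is.null(x$device)) "<none>" else x$device$manufacturer_model))
  invisible(x)
}

#' Save a CT volume to NIfTI
#'
#' Writes the voxel grid as a NIfTI-1 file (float64, lossless for HU) with
#' voxel spacing in `pixdim` and the volume origin in the qform offset.
#' Device metadata and patient id, which NIfTI cannot carry, go to a JSON
#' sidecar `<path>.meta.json` next to the image. `load_volume()` of the
#' written file reproduces voxels, spacing and origin exactly.
#'
#' @param vol a [ct_volume()].
#' @param path output filename (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(paste0("directory does not exist: ", dir))
  ok <- file.access(dir, mode = 2) == 0
  if (!ok) abort(paste0("path not writable: ", path))
  # internal order (z, y, x) -> NIfTI order (x, y, z)
  arr <- aperm(vol$voxels, c(3, 2, 1))
  sp <- vol$spacing_mm
  hdr <- RNifti::niftiHeader(list(
    pixdim = c(1, sp[3], sp[2], sp[1], 0, 0, 0, 0),
    qform_code = 2L,
    qoffset_x = vol$origin_mm[3],
    qoffset_y = vol$origin_mm[2],
    qoffset_z = vol$origin_mm[1]
  ))
  img <- RNifti::asNifti(arr, reference = hdr, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  meta <- list(
    patient_id = vol$patient_id,
    device = if (is.null(vol$device)) NULL else unclass(vol$device)
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a CT volume
#'
#' Reads a CT volume from a NIfTI file or a DICOM series directory and
#' returns a [ct_volume()] in HU. For DICOM input the stored pixel values are
#' rescaled to HU with the header slope/intercept and slices are sorted by
#' physical z position (ascending, i.e. toward the head). Only axial,
#' orthogonal, single-series CT acquisitions are supported; oblique or
#' multi-series input is rejected rather than resampled so that densitometric
#' geometry stays exact.
#'
#' @param path a NIfTI file or a directory containing one DICOM series.
#' @param format `"auto"` (default; directories are treated as DICOM),
#'   `"nifti"` or `"dicom_dir"`.
#' @return a [ct_volume()].
#' @export
load_volume <- function(path, format = c("auto", "nifti", "dicom_dir")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("input does not exist: ", path))
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_dir" else "nifti"
  }
  if (format == "dicom_dir") {
    return(read_dicom_series(path))
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) abort("ambiguous input: NIfTI volume is not 3-D")
  sp <- RNifti::pixdim(img)
  hdr <- RNifti::niftiHeader(img)
  arr <- array(as.numeric(img), dim = d)        # strip niftiImage attributes
  vox <- aperm(arr, c(3, 2, 1))                 # (x,y,z) -> (z,y,x)
  meta_path <- paste0(path, ".meta.json")
  patient_id <- "anonymous"; device <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$patient_id)) patient_id <- meta$patient_id
    if (!is.null(meta$device)) device <- do.call(device_meta, meta$device)
  }
  ct_volume(vox,
            spacing_mm = c(sp[3], sp[2], sp[1]),
            origin_mm = c(hdr$qoffset_z, hdr$qoffset_y, hdr$qoffset_x),
            device = device, patient_id = patient_id)
}

# mm coordinate of voxel centers along one axis (1-based index i -> (i-0.5)*d)
axis_mm <- function(n, d) (seq_len(n) - 0.5) * d
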