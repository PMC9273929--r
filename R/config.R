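#' Default analysis configuration
#'
#' All tunables of the measurement pipeline in one hierarchical list: HU
#' windows and thresholds used by ROI placement, reference equivalent
#' densities for the internal calibration, diagnostic category thresholds,
#' and ROC options. Every field can be overridden either programmatically
#' (`plqct_config(roi = list(margin_mm = 5))`) or from a YAML file via
#' [read_config()]. Unknown keys are rejected so typos never silently fall
#' back to defaults.
#'
#' Fields (units in names):
#' \describe{
#'   \item{roi$bone_hu_threshold}{HU above which a voxel counts as bone for
#'     vertebral localization (default 200).}
#'   \item{roi$cortical_hu_threshold}{HU above which a voxel counts as
#'     cortical-level mineral for the trabecular safety margin (default 400).}
#'   \item{roi$margin_mm}{minimum distance from any trabecular-ROI voxel to a
#'     cortical-level voxel (default 3 mm).}
#'   \item{roi$slice_span_mm}{craniocaudal extent of ROIs in mm; converted to
#'     slices as `floor(span/dz)`, minimum 1 (default 9 mm).}
#'   \item{roi$fat_window, roi$muscle_window}{HU windows for tissue candidate
#'     masks (defaults [-190, -30] and [10, 100]).}
#'   \item{roi$muscle_lateral_mm}{paraspinal search corridor half-width lateral
#'     of the vertebral midline (default 60 mm).}
#'   \item{roi$subcut_depth_mm}{maximum depth below the skin surface for the
#'     subcutaneous fat search (default 30 mm).}
#'   \item{roi$corridor_halfwidth_mm}{half-width of the posterior midline
#'     corridor used when searching for the spine (default 45 mm).}
#'   \item{roi$min_roi_voxels}{ROIs below this voxel count are flagged
#'     unreliable (default 50).}
#'   \item{roi$min_tissue_area_mm2}{minimum in-plane area of a tissue
#'     component before an ROI is placed in it (default 150 mm^2).}
#'   \item{roi$inscribe_scale}{shrink factor applied to the inscribed ellipse
#'     of a tissue component (default 0.8).}
#'   \item{roi$trim_fraction}{fraction trimmed from each tail of the ROI HU
#'     distribution before mean/SD (default 0.05).}
#'   \item{calibration$rho_fat_mgcc, calibration$rho_muscle_mgcc}{reference
#'     equivalent densities assigned to subcutaneous fat and paraspinal muscle
#'     (defaults -50 and +40 mg/cc; literature-range values, configurable).}
#'   \item{calibration$min_tissue_contrast_hu}{minimum fat/muscle HU
#'     separation for a usable calibration (default 10 HU).}
#'   \item{classification$qct_thresholds_mgcc}{ACR volumetric thresholds
#'     (default c(80, 120) mg/cc).}
#'   \item{classification$dxa_thresholds_t}{WHO T-score thresholds
#'     (default c(-2.5, -1.0)).}
#'   \item{roc$ci_method}{"delong" (default) or "bootstrap".}
#'   \item{roc$n_boot}{bootstrap replicates when ci_method = "bootstrap".}
#'   \item{seed}{seed used by randomized procedures (bootstrap CI).}
#' }
#'
#' @param ... named overrides; each name must be a top-level config section
#'   (or `seed`), each value a named list of fields to replace.
#' @return a nested list of class `plqct_config`.
#' @export
#' @examples
#' cfg <- plqct_config(roi = list(margin_mm = 4))
#' cfg$roi$margin_mm
plqct_config <- function(...) {
  cfg <- list(
    roi = list(
      bone_hu_threshold = 200,
      cortical_hu_threshold = 400,
      margin_mm = 3,
      slice_span_mm = 9,
      fat_window = c(-190, -30),
      muscle_window = c(10, 100),
      muscle_lateral_mm = 60,
      subcut_depth_mm = 30,
      corridor_halfwidth_mm = 45,
      min_bone_area_mm2 = 50,
      min_roi_voxels = 50,
      min_tissue_area_mm2 = 150,
      inscribe_scale = 0.8,
      trim_fraction = 0.05
    ),
    calibration = list(
      rho_fat_mgcc = -50,
      rho_muscle_mgcc = 40,
      min_tissue_contrast_hu = 10
    ),
    classification = list(
      qct_thresholds_mgcc = c(80, 120),
      dxa_thresholds_t = c(-2.5, -1.0)
    ),
    roc = list(
      ci_method = "delong",
      n_boot = 2000
    ),
    seed = 1L
  )
  cfg <- merge_config(cfg, list(...))
  structure(cfg, class = c("plqct_config", "list"))
}

# Recursive merge with strict key checking: overriding an unknown key is an
# error, not a silent extension.
merge_config <- function(base, overrides, path = character()) {
  if (length(overrides) == 0) return(base)
  nms <- names(overrides)
  if (is.null(nms) || any(nms == "")) {
    abort("config overrides must be named")
  }
  for (nm in nms) {
    here <- paste(c(path, nm), collapse = "$")
    if (!nm %in% names(base)) {
      abort(paste0("unknown config key: ", here))
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(overrides[[nm]])) {
        abort(paste0("config section '", here, "' must be a named list"))
      }
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]], c(path, nm))
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Read a configuration file
#'
#' Loads a YAML document and overlays it on [plqct_config()] defaults.
#' Unknown keys raise an error naming the offending field.
#'
#' @param path YAML file.
#' @return a `plqct_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  do.call(plqct_config, doc)
}

#' @export
print.plqct_config <- function(x, ...) {
  cat("<plqct_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

as_config <- function(config) {
  if (is.null(config)) return(plqct_config())
  if (inherits(config, "plqct_config")) return(config)
  if (is.list(config)) return(do.call(plqct_config, config))
  abort("config must be NULL, a plqct_config, or a named list of overrides")
}
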