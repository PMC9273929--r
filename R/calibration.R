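# Internal two-tissue calibration: the core HU -> vBMD conversion.

#' Fit the internal fat/muscle calibration
#'
#' Phantom-less QCT replaces the external reference phantom with two tissues
#' present in every chest scan: subcutaneous fat and paraspinal muscle. Their
#' measured HU are anchored to reference equivalent densities
#' (`rho_fat`, `rho_muscle`, mg/cc), giving the exact two-point line
#' \deqn{slope = (\rho_m - \rho_f)/(H_m - H_f), \quad
#'       intercept = \rho_f - slope \cdot H_f.}
#' Because both anchors come from the same scan, scanner-specific offsets in
#' the HU scale cancel out of the density estimate.
#'
#' @param hu_fat,hu_muscle measured mean HU of the fat and muscle ROIs.
#' @param rho_fat,rho_muscle reference equivalent densities in mg/cc
#'   (defaults -50 and +40; configurable, see [plqct_config()]).
#' @param min_contrast_hu minimum muscle-fat HU separation below which the
#'   calibration is rejected as unreliable (default 10 HU).
#' @return an object of class `calibration_model` with fields `slope`
#'   (mg/cc per HU), `intercept` (mg/cc), and the four anchor values.
#' @export
#' @examples
#' m <- fit_internal_calibration(-100, 50, rho_fat = 0, rho_muscle = 150)
#' c(m$slope, m$intercept)  # 1, 100
fit_internal_calibration <- function(hu_fat, hu_muscle,
                                     rho_fat = -50, rho_muscle = 40,
                                     min_contrast_hu = 10) {
  vals <- c(hu_fat, hu_muscle, rho_fat, rho_muscle)
  if (length(vals) != 4 || any(!is.finite(vals))) {
    abort("calibration inputs must be finite scalars")
  }
  if (hu_muscle <= hu_fat) {
    abort("degenerate tissue contrast: muscle HU must exceed fat HU")
  }
  if (abs(hu_muscle - hu_fat) < min_contrast_hu) {
    abort(paste0("degenerate tissue contrast: |H_muscle - H_fat| < ",
                 min_contrast_hu, " HU"))
  }
  slope <- (rho_muscle - rho_fat) / (hu_muscle - hu_fat)
  structure(
    list(slope = slope,
         intercept = rho_fat - slope * hu_fat,
         hu_fat = hu_fat, hu_muscle = hu_muscle,
         rho_fat = rho_fat, rho_muscle = rho_muscle),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> vBMD = %.4f * HU + %.2f  (fat %.1f HU -> %.1f mg/cc; muscle %.1f HU -> %.1f mg/cc)\n",
    x$slope, x$intercept, x$hu_fat, x$rho_fat, x$hu_muscle, x$rho_muscle))
  invisible(x)
}

#' Convert trabecular HU to vBMD
#'
#' @param model a [fit_internal_calibration()] model.
#' @param hu_trab trabecular HU (vectorized).
#' @return vBMD in mg/cc. Negative values are possible for pathologic inputs
#'   and are reported as-is (callers flag them); they are never clamped.
#' @export
apply_calibration <- function(model, hu_trab) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(!is.finite(hu_trab))) abort("hu_trab must be finite")
  model$slope * hu_trab + model$intercept
}

#' Measure vertebral trabecular vBMD from a chest CT volume
#'
#' The full phantom-less pipeline: locate the vertebral level, place the
#' trabecular ROI and the fat/paraspinal-muscle calibration ROIs, compute
#' trimmed ROI statistics, fit the internal two-tissue calibration, convert
#' trabecular HU to vBMD and classify the result. Muscle HU is the mean of
#' the left and right paraspinal ROI means. Errors from any stage are
#' re-raised with a stage tag (e.g. `[locate] ...`).
#'
#' @param vol a [ct_volume()].
#' @param config a [plqct_config()] (or named overrides).
#' @param level vertebral level label passed to [locate_vertebral_level()].
#' @return an object of class `bmd_result`: fields `patient_id`,
#'   `vbmd_mgcc`, `category`, `roi_stats` (tibble, one row per ROI),
#'   `calibration` (the fitted model, for audit), `rois`, `center_voxel`,
#'   `flags` (character; e.g. `"negative_vbmd"`, `"roi_unreliable"`).
#' @export
measure_vbmd <- function(vol, config = NULL, level = "T12") {
  cfg <- as_config(config)
  stage <- function(tag, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", tag, "] ", conditionMessage(e)))
    })
  }
  center <- stage("locate", locate_vertebral_level(vol, level = level, config = cfg))
  trab <- stage("trabecular_roi", place_trabecular_roi(vol, center, config = cfg))
  tissue <- stage("tissue_rois", place_tissue_rois(vol, center, config = cfg))
  rois <- c(list(trabecular = trab), tissue)
  stats <- stage("roi_stats", dplyr::bind_rows(lapply(
    rois, roi_statistics, vol = vol,
    trim_fraction = cfg$roi$trim_fraction,
    min_voxels = cfg$roi$min_roi_voxels
  )))
  hu_of <- function(lbl) stats$mean_hu[stats$label == lbl]
  hu_muscle <- mean(c(hu_of("muscle_left"), hu_of("muscle_right")))
  model <- stage("calibration", fit_internal_calibration(
    hu_fat = hu_of("fat"), hu_muscle = hu_muscle,
    rho_fat = cfg$calibration$rho_fat_mgcc,
    rho_muscle = cfg$calibration$rho_muscle_mgcc,
    min_contrast_hu = cfg$calibration$min_tissue_contrast_hu
  ))
  vbmd <- apply_calibration(model, hu_of("trabecular"))
  category <- classify_qct(vbmd, cfg$classification$qct_thresholds_mgcc)
  flags <- character()
  if (vbmd < 0) flags <- c(flags, "negative_vbmd")
  if (any(stats$unreliable)) flags <- c(flags, "roi_unreliable")
  structure(
    list(patient_id = vol$patient_id,
         vbmd_mgcc = vbmd,
         category = category,
         roi_stats = stats,
         calibration = model,
         rois = rois,
         center_voxel = center,
         level = level,
         flags = flags),
    class = "bmd_result"
  )
}

#' @export
print.bmd_result <- function(x, ...) {
  cat(sprintf("<bmd_result> %s: vBMD %.1f mg/cc (%s)%s\n",
              x$patient_id, x$vbmd_mgcc, as.character(x$category),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Fit a per-device HU-vBMD regression
#'
#' Ordinary least-squares line and Pearson correlation between trabecular CT
#' attenuation and calibrated vBMD for one scanner. Raw HU cannot be compared
#' across scanners; these per-device regressions quantify how the linear
#' HU-density response differs between machines.
#'
#' @param hu trabecular HU values.
#' @param vbmd matched vBMD values, mg/cc.
#' @param device device label.
#' @return an object of class `device_regression`: `device, slope, intercept,
#'   pearson_r, n`.
#' @export
fit_device_regression <- function(hu, vbmd, device = "unknown") {
  ok <- is.finite(hu) & is.finite(vbmd)
  hu <- hu[ok]; vbmd <- vbmd[ok]
  n <- length(hu)
  if (n < 3 || length(vbmd) != n) {
    abort("need >= 3 paired finite observations")
  }
  if (var(hu) == 0) abort("zero variance in hu: correlation undefined")
  fit <- stats::lm(vbmd ~ hu)
  structure(
    list(device = as.character(device),
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         pearson_r = if (var(vbmd) == 0) NA_real_ else cor(hu, vbmd),
         n = n),
    class = "device_regression"
  )
}

#' @export
print.device_regression <- function(x, ...) {
  cat(sprintf("<device_regression> %s: vBMD = %.3f * HU + %.2f, r = %.3f (n = %d)\n",
              x$device, x$slope, x$intercept, x$pearson_r, x$n))
  invisible(x)
}
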