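# broom-style tidiers for the package's fitted objects.

#' @rdname tidy.calibration_model
#' @export
tidy.calibration_model <- function(x, ...) {
  tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    unit = c("mg/cc per HU", "mg/cc")
  )
}

#' Tidy and glance methods
#'
#' One-line summaries of the package's result objects in the broom idiom:
#' `tidy()` returns per-term or per-row tibbles, `glance()` a one-row model
#' summary.
#'
#' @param x a `calibration_model`, `device_regression`, `plqct_roc` or
#'   `bmd_result`.
#' @param ... unused.
#' @return a tibble.
#' @name tidy.calibration_model
NULL

#' @rdname tidy.calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         hu_fat = x$hu_fat, hu_muscle = x$hu_muscle,
         rho_fat = x$rho_fat, rho_muscle = x$rho_muscle)
}

#' @rdname tidy.calibration_model
#' @export
tidy.device_regression <- function(x, ...) {
  tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept)
  )
}

#' @rdname tidy.calibration_model
#' @export
glance.device_regression <- function(x, ...) {
  tibble(device = x$device, slope = x$slope, intercept = x$intercept,
         pearson_r = x$pearson_r, n = x$n)
}

#' @rdname tidy.calibration_model
#' @export
tidy.plqct_roc <- function(x, ...) x$curve

#' @rdname tidy.calibration_model
#' @export
glance.plqct_roc <- function(x, ...) {
  tibble(
    auc = x$auc, ci95_low = x$ci95_low, ci95_high = x$ci95_high,
    sensitivity_pct = x$sensitivity_pct, specificity_pct = x$specificity_pct,
    youden_j = x$youden_j, associated_criterion = x$associated_criterion,
    criterion_direction = x$criterion_direction,
    n = x$n, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @rdname tidy.calibration_model
#' @export
tidy.bmd_result <- function(x, ...) {
  hu_of <- function(lbl) x$roi_stats$mean_hu[x$roi_stats$label == lbl]
  tibble(
    patient_id = x$patient_id,
    vbmd_mgcc = x$vbmd_mgcc,
    category = as.character(x$category),
    hu_trab = hu_of("trabecular"),
    hu_fat = hu_of("fat"),
    hu_muscle = mean(c(hu_of("muscle_left"), hu_of("muscle_right"))),
    slope = x$calibration$slope,
    intercept = x$calibration$intercept,
    flags = paste(x$flags, collapse = ";")
  )
}
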