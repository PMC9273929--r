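# Diagnostic categories from QCT vBMD (ACR thresholds) and DXA T-scores
# (WHO criteria).

#' Diagnostic category levels
#'
#' Ordered from healthy to diseased: normal, osteopenia, osteoporosis.
#' @return character vector of the three levels.
#' @export
bmd_categories <- function() c("normal", "osteopenia", "osteoporosis")

as_category <- function(x) {
  factor(x, levels = bmd_categories(), ordered = TRUE)
}

#' Classify volumetric BMD (QCT)
#'
#' ACR volumetric criteria: vBMD below 80 mg/cc is osteoporosis, above
#' 120 mg/cc is normal, and osteopenia covers the closed interval
#' `[80, 120]`. The endpoint convention (both boundaries count as
#' osteopenia) is a documented package choice; the thresholds are
#' configurable.
#'
#' @param vbmd_mgcc vBMD values, mg/cc (vectorized).
#' @param thresholds `c(osteoporosis_below, normal_above)`, default
#'   `c(80, 120)`.
#' @return ordered factor with levels [bmd_categories()].
#' @export
#' @examples
#' classify_qct(c(79.9, 80, 120, 150))
classify_qct <- function(vbmd_mgcc, thresholds = c(80, 120)) {
  if (any(!is.finite(vbmd_mgcc))) abort("vbmd_mgcc must be finite")
  if (length(thresholds) != 2 || thresholds[1] >= thresholds[2]) {
    abort("thresholds must be c(lower, upper) with lower < upper")
  }
  out <- ifelse(vbmd_mgcc < thresholds[1], "osteoporosis",
                ifelse(vbmd_mgcc <= thresholds[2], "osteopenia", "normal"))
  as_category(out)
}

#' Classify a DXA T-score
#'
#' WHO criteria: T-score of -2.5 or below is osteoporosis; between -2.5
#' (exclusive) and -1.0 (inclusive) is osteopenia; above -1.0 is normal.
#'
#' @param t_score DXA T-score(s).
#' @param thresholds `c(osteoporosis_at_or_below, osteopenia_at_or_below)`,
#'   default `c(-2.5, -1.0)`.
#' @return ordered factor with levels [bmd_categories()].
#' @export
#' @examples
#' classify_dxa(c(-2.5, -1.0, 0))
classify_dxa <- function(t_score, thresholds = c(-2.5, -1.0)) {
  if (any(!is.finite(t_score))) abort("t_score must be finite")
  if (length(thresholds) != 2 || thresholds[1] >= thresholds[2]) {
    abort("thresholds must be c(lower, upper) with lower < upper")
  }
  out <- ifelse(t_score <= thresholds[1], "osteoporosis",
                ifelse(t_score <= thresholds[2], "osteopenia", "normal"))
  as_category(out)
}

#' Composite DXA label from spine and hip T-scores
#'
#' Clinical practice diagnoses from the lower of the spine and hip DXA
#' T-scores; this composite is the third reference standard in the
#' evaluation. Vectorized over records; `NA` marks an absent site
#' measurement, and a record with both sites absent is an error (such
#' records should have been excluded as DXA-incomplete).
#'
#' @param spine_t,hip_t site T-scores (`NA` = absent).
#' @param thresholds passed to [classify_dxa()].
#' @return a tibble: `spine_t, hip_t, composite_t, category`.
#' @export
#' @examples
#' composite_dxa_label(-1.2, -2.7)$category
composite_dxa_label <- function(spine_t, hip_t, thresholds = c(-2.5, -1.0)) {
  if (length(spine_t) != length(hip_t)) abort("spine_t and hip_t lengths differ")
  both_absent <- is.na(spine_t) & is.na(hip_t)
  if (any(both_absent)) {
    abort(paste0("no DXA reference for ", sum(both_absent),
                 " record(s): both site T-scores absent"))
  }
  composite <- pmin(spine_t, hip_t, na.rm = TRUE)
  tibble(
    spine_t = spine_t, hip_t = hip_t, composite_t = composite,
    category = classify_dxa(composite, thresholds)
  )
}
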