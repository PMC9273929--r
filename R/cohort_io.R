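# Cohort table schema. One row per patient; missing cells are NA (explicit
# absence used by the exclusion logic), never silent zeros.
COHORT_COLUMNS <- c(
  patient_id = "character",
  age = "numeric",
  sex = "character",
  height_cm = "numeric",
  weight_kg = "numeric",
  bmi = "numeric",
  spine_dxa_t = "numeric",
  fn_dxa_t = "numeric",
  th_dxa_t = "numeric",
  spine_dxa_bmd = "numeric",
  hip_dxa_bmd = "numeric",
  qct_vbmd = "numeric",
  device = "character",
  has_ldct = "logical",
  has_t12 = "logical",
  dxa_complete = "logical"
)

#' Load a cohort table
#'
#' Reads a per-patient CSV with the documented schema (see Details) into a
#' typed tibble. Unknown columns and unparseable numerics are errors; missing
#' cells become `NA`. `bmi` is computed from height/weight when absent, and
#' `dxa_complete` is derived as "all three DXA T-scores present" when the
#' file does not carry the flag explicitly.
#'
#' @details Recognised columns: `patient_id, age, sex (M/F), height_cm,
#'   weight_kg, bmi, spine_dxa_t, fn_dxa_t, th_dxa_t, spine_dxa_bmd,
#'   hip_dxa_bmd, qct_vbmd, device, has_ldct, has_t12, dxa_complete`.
#'   Only `patient_id`, `age` and `sex` are required.
#'
#' @param path CSV file with a header row.
#' @return a tibble with one row per patient.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  unknown <- setdiff(hdr, names(COHORT_COLUMNS))
  if (length(unknown) > 0) {
    abort(paste0("unknown cohort column(s): ", paste(unknown, collapse = ", ")))
  }
  required <- c("patient_id", "age", "sex")
  missing_req <- setdiff(required, hdr)
  if (length(missing_req) > 0) {
    abort(paste0("cohort file lacks required column(s): ",
                 paste(missing_req, collapse = ", ")))
  }
  spec <- do.call(readr::cols, c(
    lapply(COHORT_COLUMNS[hdr], function(tp) switch(
      tp,
      character = readr::col_character(),
      numeric = readr::col_double(),
      logical = readr::col_logical()
    )),
    list(.default = readr::col_skip())
  ))
  tbl <- suppressWarnings(
    readr::read_csv(path, col_types = spec, show_col_types = FALSE))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(paste0("unparseable value(s) in cohort file, e.g. row ",
                 probs$row[1], ": expected ", probs$expected[1],
                 ", got '", probs$actual[1], "'"))
  }
  validate_cohort(tbl)
}

validate_cohort <- function(tbl) {
  for (col in names(COHORT_COLUMNS)) {
    if (!col %in% names(tbl)) {
      tbl[[col]] <- switch(COHORT_COLUMNS[[col]],
                           character = NA_character_,
                           numeric = NA_real_,
                           logical = NA)
    }
  }
  bad_sex <- !is.na(tbl$sex) & !tbl$sex %in% c("M", "F")
  if (any(bad_sex)) {
    abort(paste0("sex must be 'M' or 'F'; offending value(s): ",
                 paste(unique(tbl$sex[bad_sex]), collapse = ", ")))
  }
  if (any(!is.na(tbl$age) & tbl$age < 0)) abort("age must be >= 0")
  computed_bmi <- tbl$weight_kg / (tbl$height_cm / 100)^2
  tbl$bmi <- dplyr::coalesce(tbl$bmi, computed_bmi)
  inconsistent <- !is.na(tbl$bmi) & !is.na(computed_bmi) &
    abs(tbl$bmi - computed_bmi) > 0.1
  if (any(inconsistent)) {
    warn(paste0(sum(inconsistent),
                " record(s) have BMI inconsistent with height/weight by > 0.1"))
  }
  tbl$has_ldct <- dplyr::coalesce(tbl$has_ldct, TRUE)
  tbl$has_t12 <- dplyr::coalesce(tbl$has_t12, TRUE)
  derived_complete <- !is.na(tbl$spine_dxa_t) & !is.na(tbl$fn_dxa_t) &
    !is.na(tbl$th_dxa_t)
  tbl$dxa_complete <- dplyr::coalesce(tbl$dxa_complete, derived_complete)
  tbl[, names(COHORT_COLUMNS)]
}

#' Write a cohort table
#'
#' @param cohort a cohort tibble (as from [load_cohort()] or
#'   [generate_cohort()]; ground-truth columns, whose names start with a dot,
#'   are dropped so the file matches what a real registry would hold).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  keep <- intersect(names(COHORT_COLUMNS), names(cohort))
  readr::write_csv(cohort[, keep], path, na = "")
  invisible(path)
}
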