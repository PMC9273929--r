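# Cohort-level evaluation: exclusion flow, demographic summaries, confusion
# matrices, age-stratified density trends and precision metrics.

EXCLUSION_REASONS <- c("no_ldct", "no_t12", "dxa_incomplete")

#' Apply the cohort exclusion flow
#'
#' Partitions a roster into included and excluded records. Each excluded
#' patient receives exactly one reason, assigned in priority order:
#' (1) no low-dose CT available (`has_ldct` FALSE), (2) the measured
#' vertebral level not covered (`has_t12` FALSE), (3) incomplete DXA
#' (`dxa_complete` FALSE). Reasons are therefore mutually exclusive and
#' exhaustive, and `nrow(included) + nrow(excluded) == nrow(roster)`.
#'
#' @param roster a cohort tibble (see [load_cohort()]).
#' @return a list: `included` (tibble), `excluded` (tibble with a `reason`
#'   column), `tally` (tibble `reason, n`, all three reasons always present).
#' @export
apply_exclusions <- function(roster) {
  if (nrow(roster) == 0) abort("roster is empty")
  roster <- validate_cohort(roster)
  reason <- dplyr::case_when(
    !roster$has_ldct ~ "no_ldct",
    !roster$has_t12 ~ "no_t12",
    !roster$dxa_complete ~ "dxa_incomplete",
    TRUE ~ NA_character_
  )
  excluded <- roster[!is.na(reason), , drop = FALSE]
  excluded$reason <- factor(reason[!is.na(reason)], levels = EXCLUSION_REASONS)
  tally <- excluded |>
    dplyr::count(.data$reason, .drop = FALSE, name = "n") |>
    dplyr::rename(reason = "reason")
  list(
    included = roster[is.na(reason), , drop = FALSE],
    excluded = excluded,
    tally = tibble::as_tibble(tally)
  )
}

#' Demographic summary by sex and total
#'
#' Mean and sample SD (n - 1 denominator) of age, height, weight and BMI per
#' sex plus the pooled total, mirroring a standard cohort "Table 1". The
#' pooled mean over the union of records equals the count-weighted mean of
#' the subgroup means (see [pool_group_means()]).
#'
#' @param records included cohort tibble.
#' @param vars columns to summarize.
#' @return a tibble: `group` (Male/Female/Total), `variable`, `n`, `mean`,
#'   `sd`.
#' @export
cohort_summary <- function(records,
                           vars = c("age", "height_cm", "weight_kg", "bmi")) {
  if (nrow(records) == 0) abort("no records to summarize")
  missing_vars <- setdiff(vars, names(records))
  if (length(missing_vars) > 0) {
    abort(paste0("unknown variable(s): ", paste(missing_vars, collapse = ", ")))
  }
  one_group <- function(df, label) {
    purrr::map_dfr(vars, function(v) {
      x <- df[[v]][!is.na(df[[v]])]
      tibble(group = label, variable = v, n = length(x),
             mean = if (length(x) > 0) mean(x) else NA_real_,
             sd = if (length(x) > 1) sd(x) else NA_real_)
    })
  }
  dplyr::bind_rows(
    one_group(records[records$sex %in% "M", ], "Male"),
    one_group(records[records$sex %in% "F", ], "Female"),
    one_group(records, "Total")
  )
}

#' Count-weighted pooled mean of subgroup means
#'
#' @param n subgroup sizes.
#' @param mean subgroup means.
#' @return the pooled mean `sum(n * mean) / sum(n)`.
#' @export
#' @examples
#' pool_group_means(c(266, 383), c(55.06, 60.02))  # 57.99
pool_group_means <- function(n, mean) {
  if (length(n) != length(mean) || any(n < 0) || sum(n) == 0) {
    abort("n and mean must match, with sum(n) > 0")
  }
  sum(n * mean) / sum(n)
}

AGE_BIN_BREAKS <- c(-Inf, 30, 40, 50, 60, 70, 80, Inf)
AGE_BIN_LABELS <- c("<30", "30-39", "40-49", "50-59", "60-69", "70-79", "80+")

#' Assign decade age bins
#'
#' Seven bins, closed on the left: `<30, 30-39, ..., 70-79, 80+`.
#' @param age numeric ages in years.
#' @return factor with the seven bin labels.
#' @export
age_bin <- function(age) {
  cut(age, breaks = AGE_BIN_BREAKS, labels = AGE_BIN_LABELS, right = FALSE)
}

#' Age-stratified BMD summary
#'
#' Per-bin, per-sex mean and sample SD of a BMD column over the seven decade
#' bins. Empty bins are reported with `n = 0` and `NA` mean (never zero);
#' single-record bins have `NA` SD.
#'
#' @param records cohort tibble with `age` and `sex`.
#' @param value column to summarize (default `qct_vbmd`), tidy-evaluated.
#' @return a tibble: `age_bin, sex, n, mean, sd`, complete over all
#'   bin-by-sex combinations.
#' @export
age_stratified_bmd <- function(records, value = "qct_vbmd") {
  if (!value %in% names(records)) abort(paste0("no column '", value, "'"))
  if (any(!is.finite(records$age))) abort("ages must be finite")
  df <- tibble(
    age_bin = age_bin(records$age),
    sex = factor(records$sex, levels = c("F", "M")),
    v = records[[value]]
  ) |>
    dplyr::filter(!is.na(.data$v))
  df |>
    dplyr::group_by(.data$age_bin, .data$sex, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = if (dplyr::n() > 0) mean(.data$v) else NA_real_,
      sd = if (dplyr::n() > 1) sd(.data$v) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(mean = ifelse(.data$n == 0, NA_real_, .data$mean))
}

#' Precision of repeated BMD measurements
#'
#' Short-term precision in the standard densitometric sense: the
#' root-mean-square of per-subject standard deviations (RMS-SD, mg/cc) and
#' the coefficient of variation CV% = RMS-SD / grand mean x 100. Subjects
#' with fewer than two repeats are skipped with a warning.
#'
#' @param repeats either a tibble with subject and value columns, or a list
#'   of per-subject numeric vectors.
#' @param subject,value column names when `repeats` is a data frame.
#' @return a one-row tibble: `n_subjects, n_measurements,
#'   precision_sd_mgcc, precision_cv_pct, grand_mean`.
#' @export
#' @examples
#' compute_precision(list(a = c(98, 102)))  # SD 2.83 mg/cc, CV 2.83%
compute_precision <- function(repeats, subject = "subject_id",
                              value = "vbmd_mgcc") {
  if (is.data.frame(repeats)) {
    if (!all(c(subject, value) %in% names(repeats))) {
      abort(paste0("repeats must have columns '", subject, "' and '", value, "'"))
    }
    groups <- split(repeats[[value]], repeats[[subject]])
  } else if (is.list(repeats)) {
    groups <- repeats
  } else {
    abort("repeats must be a data frame or a list of numeric vectors")
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2)) {
    warn(paste0(sum(sizes < 2), " subject(s) with < 2 repeats skipped"))
    groups <- groups[sizes >= 2]
  }
  if (length(groups) == 0) abort("no subject has >= 2 repeats")
  sds <- vapply(groups, sd, numeric(1))
  rms_sd <- sqrt(mean(sds^2))
  grand <- mean(unlist(groups))
  tibble(
    n_subjects = length(groups),
    n_measurements = length(unlist(groups)),
    precision_sd_mgcc = rms_sd,
    precision_cv_pct = rms_sd / grand * 100,
    grand_mean = grand
  )
}

#' Pearson product-moment correlation
#'
#' @param x,y paired numeric vectors, n >= 3, both with positive variance.
#' @return the correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need >= 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) abort("zero variance: correlation undefined")
  cor(x, y)
}

#' Three-way diagnostic confusion matrix
#'
#' Cross-tabulates predicted (QCT) against reference (DXA) categories in the
#' fixed order normal, osteopenia, osteoporosis. Rows are the reference,
#' columns the prediction. Also returns per-category diagnosis rates (column
#' and row sums as % of n) and the observed agreement (trace / n).
#'
#' @param pred_categories,ref_categories equal-length category vectors
#'   (factors or strings matching [bmd_categories()]).
#' @return an object of class `plqct_confusion`: `matrix` (3x3 counts),
#'   `n`, `pred_rates_pct`, `ref_rates_pct`, `agreement`.
#' @export
confusion_matrix_3x3 <- function(pred_categories, ref_categories) {
  if (length(pred_categories) != length(ref_categories)) {
    abort("prediction and reference lengths differ")
  }
  check_cats <- function(x, what) {
    vals <- as.character(x)
    bad <- !is.na(vals) & !vals %in% bmd_categories()
    if (any(bad)) {
      abort(paste0("unknown ", what, " category: ",
                   paste(unique(vals[bad]), collapse = ", ")))
    }
    if (any(is.na(vals))) abort(paste0("NA in ", what, " categories"))
    factor(vals, levels = bmd_categories())
  }
  pred <- check_cats(pred_categories, "predicted")
  ref <- check_cats(ref_categories, "reference")
  m <- table(reference = ref, predicted = pred)
  n <- length(pred)
  structure(
    list(matrix = unclass(m), n = n,
         pred_rates_pct = colSums(m) / n * 100,
         ref_rates_pct = rowSums(m) / n * 100,
         agreement = sum(diag(m)) / n),
    class = "plqct_confusion"
  )
}

#' @export
print.plqct_confusion <- function(x, ...) {
  cat("<plqct_confusion> rows = reference (DXA), cols = predicted (QCT)\n")
  print(x$matrix)
  cat(sprintf("agreement %.1f%% of n = %d\n", 100 * x$agreement, x$n))
  invisible(x)
}
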