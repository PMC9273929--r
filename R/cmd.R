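# High-level commands binding the pipeline together. These are the
# programmatic counterparts of the `plqct` command-line entry point
# (inst/cli/plqct.R).

#' Measure vBMD for one or more volumes
#'
#' Runs [measure_vbmd()] on each input (NIfTI files, DICOM directories, or a
#' directory of NIfTI files, processed in filename order), writes one JSON
#' result per volume plus a combined `results.csv` when `out_dir` is given,
#' and returns a tibble with one row per input. A failing volume does not
#' stop the batch: its row carries the stage-tagged error message and the
#' count of failures is attached as attribute `"n_failed"`.
#'
#' @param inputs character vector of volume paths, or a single directory.
#' @param out_dir optional output directory.
#' @param config a [plqct_config()] (or named overrides).
#' @return a tibble: `input, patient_id, vbmd_mgcc, category, hu_trab,
#'   hu_fat, hu_muscle, slope, intercept, flags, error`.
#' @export
cmd_measure <- function(inputs, out_dir = NULL, config = NULL) {
  cfg <- as_config(config)
  if (length(inputs) == 1 && dir.exists(inputs) &&
      !any(grepl("\\.dcm$", list.files(inputs)))) {
    inputs <- sort(list.files(inputs, pattern = "\\.nii(\\.gz)?$",
                              full.names = TRUE))
  }
  if (length(inputs) == 0) abort("no input volumes")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- purrr::map(sort(inputs), function(p) {
    res <- tryCatch({
      vol <- suppressWarnings(load_volume(p))   # a corrupt file is an error, not noise
      r <- measure_vbmd(vol, config = cfg)
      row <- tidy(r)
      if (!is.null(out_dir)) {
        base <- sub("\\.nii(\\.gz)?$", "", basename(p))
        jsonlite::write_json(
          c(list(input = p), as.list(row)),
          file.path(out_dir, paste0(base, ".bmd.json")),
          auto_unbox = TRUE, digits = NA)
      }
      dplyr::mutate(row, input = p, error = NA_character_, .before = 1)
    }, error = function(e) {
      tibble(input = p, patient_id = NA_character_, vbmd_mgcc = NA_real_,
             category = NA_character_, hu_trab = NA_real_, hu_fat = NA_real_,
             hu_muscle = NA_real_, slope = NA_real_, intercept = NA_real_,
             flags = NA_character_, error = conditionMessage(e))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    readr::write_csv(out, file.path(out_dir, "results.csv"), na = "")
  }
  attr(out, "n_failed") <- sum(!is.na(out$error))
  out
}

roc_subgroups <- function(cohort, cfg) {
  refs <- list(
    hip = pmin(cohort$fn_dxa_t, cohort$th_dxa_t),
    spine = cohort$spine_dxa_t,
    lower = composite_dxa_label(cohort$spine_dxa_t,
                                pmin(cohort$fn_dxa_t, cohort$th_dxa_t),
                                cfg$classification$dxa_thresholds_t)$composite_t
  )
  groups <- list(women = cohort$sex == "F", men = cohort$sex == "M",
                 total = rep(TRUE, nrow(cohort)))
  grid <- tidyr::expand_grid(
    reference = names(refs), group = names(groups),
    diagnosis = c("osteoporosis", "osteopenia"))
  purrr::pmap_dfr(grid, function(reference, group, diagnosis) {
    keep <- groups[[group]]
    tv <- refs[[reference]][keep]
    cat_ref <- classify_dxa(tv, cfg$classification$dxa_thresholds_t)
    positive <- if (diagnosis == "osteoporosis") {
      cat_ref == "osteoporosis"
    } else {
      cat_ref %in% c("osteopenia", "osteoporosis")   # any bone loss vs normal
    }
    base <- tibble(reference = reference, group = group, diagnosis = diagnosis,
                   n = sum(keep))
    r <- tryCatch(
      roc_analysis(cohort$qct_vbmd[keep], positive,
                   ci_method = cfg$roc$ci_method,
                   n_boot = cfg$roc$n_boot, seed = cfg$seed),
      error = function(e) NULL)
    if (is.null(r)) {
      dplyr::mutate(base, auc = NA_real_, ci95_low = NA_real_,
                    ci95_high = NA_real_, sensitivity_pct = NA_real_,
                    specificity_pct = NA_real_, youden_j = NA_real_,
                    associated_criterion = NA_real_, degenerate = TRUE)
    } else {
      dplyr::mutate(base, auc = r$auc, ci95_low = r$ci95_low,
                    ci95_high = r$ci95_high,
                    sensitivity_pct = r$sensitivity_pct,
                    specificity_pct = r$specificity_pct,
                    youden_j = r$youden_j,
                    associated_criterion = r$associated_criterion,
                    degenerate = FALSE)
    }
  })
}

#' Evaluate a cohort against DXA reference standards
#'
#' The full diagnostic evaluation: exclusion flow, demographic summary,
#' ROC per reference standard (hip, spine, lower-of-both) by sex and
#' diagnosis, the QCT-vs-DXA confusion matrix, and the age-stratified BMD
#' table. Reruns with the same config and seed are byte-identical.
#'
#' @param cohort a cohort tibble or CSV path.
#' @param out_dir optional output directory (writes `report.json`,
#'   `report.md`, `confusion.csv`, `roc.csv`, `age_strata.csv`).
#' @param reference which composite drives the confusion matrix:
#'   `"spine"` (default; the classic QCT-vs-spine-DXA comparison),
#'   `"hip"`, or `"lower"`.
#' @param config a [plqct_config()] (or named overrides).
#' @return an object of class `plqct_report` (a named list with elements
#'   `exclusions`, `summary`, `roc`, `confusion`, `age_strata`,
#'   `reference`, `n_included`).
#' @export
cmd_evaluate <- function(cohort, out_dir = NULL,
                         reference = c("spine", "hip", "lower"),
                         config = NULL) {
  reference <- match.arg(reference)
  cfg <- as_config(config)
  if (is.character(cohort)) cohort <- load_cohort(cohort)
  excl <- apply_exclusions(cohort)
  inc <- excl$included
  if (nrow(inc) == 0) abort("no records remain after exclusions")

  summary_tbl <- cohort_summary(inc)
  roc_tbl <- roc_subgroups(inc, cfg)

  ref_t <- switch(reference,
    spine = inc$spine_dxa_t,
    hip = pmin(inc$fn_dxa_t, inc$th_dxa_t),
    lower = composite_dxa_label(inc$spine_dxa_t,
                                pmin(inc$fn_dxa_t, inc$th_dxa_t),
                                cfg$classification$dxa_thresholds_t)$composite_t)
  usable <- is.finite(inc$qct_vbmd) & is.finite(ref_t)
  conf <- confusion_matrix_3x3(
    classify_qct(inc$qct_vbmd[usable], cfg$classification$qct_thresholds_mgcc),
    classify_dxa(ref_t[usable], cfg$classification$dxa_thresholds_t))
  strata <- age_stratified_bmd(inc)

  report <- structure(
    list(
      n_roster = nrow(cohort),
      n_included = nrow(inc),
      exclusions = excl$tally,
      summary = summary_tbl,
      roc = roc_tbl,
      confusion = conf,
      age_strata = strata,
      reference = reference,
      config = unclass(cfg)
    ),
    class = "plqct_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  payload <- report
  payload$confusion <- list(
    matrix = report$confusion$matrix, n = report$confusion$n,
    pred_rates_pct = as.list(report$confusion$pred_rates_pct),
    ref_rates_pct = as.list(report$confusion$ref_rates_pct),
    agreement = report$confusion$agreement)
  jsonlite::write_json(unclass(payload), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  readr::write_csv(report$roc, file.path(out_dir, "roc.csv"), na = "")
  readr::write_csv(report$age_strata, file.path(out_dir, "age_strata.csv"), na = "")
  cm <- as.data.frame.matrix(report$confusion$matrix)
  cm <- cbind(reference = rownames(cm), cm)
  readr::write_csv(tibble::as_tibble(cm), file.path(out_dir, "confusion.csv"))
  writeLines(format_report_md(report), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

format_report_md <- function(report) {
  tal <- report$exclusions
  c(
    "# Phantom-less QCT evaluation report",
    "",
    sprintf("Roster: %d; included: %d; excluded: %d (%s).",
            report$n_roster, report$n_included,
            report$n_roster - report$n_included,
            paste(sprintf("%s %d", tal$reason, tal$n), collapse = ", ")),
    "",
    "## Demographics (mean, SD)",
    "",
    paste(utils::capture.output(print(as.data.frame(report$summary))),
          collapse = "\n"),
    "",
    sprintf("## ROC (QCT vBMD vs DXA reference standards; confusion reference: %s DXA)",
            report$reference),
    "",
    paste(utils::capture.output(print(as.data.frame(report$roc))),
          collapse = "\n"),
    "",
    "## Confusion matrix (rows = DXA reference, cols = QCT prediction)",
    "",
    paste(utils::capture.output(print(report$confusion$matrix)),
          collapse = "\n"),
    "",
    "## Age-stratified QCT vBMD",
    "",
    paste(utils::capture.output(print(as.data.frame(report$age_strata))),
          collapse = "\n")
  )
}

#' @export
print.plqct_report <- function(x, ...) {
  cat(sprintf("<plqct_report> %d/%d included; reference: %s DXA\n",
              x$n_included, x$n_roster, x$reference))
  cat(sprintf("  QCT/DXA agreement %.1f%%; %d ROC rows\n",
              100 * x$confusion$agreement, nrow(x$roc)))
  invisible(x)
}

#' Generate simulation fixtures
#'
#' Writes a phantom (NIfTI + JSON manifest), a multi-vertebra phantom, or a
#' cohort (CSV + JSON ground-truth table) to `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param what `"phantom"`, `"multi"`, or `"cohort"`.
#' @param seed RNG seed.
#' @param spec optional [phantom_spec()] (phantom/multi).
#' @param model optional [cohort_model()] (cohort).
#' @param n_bodies bodies for `"multi"` (default 3).
#' @return invisibly, the paths written.
#' @export
cmd_simulate <- function(out_dir, what = c("phantom", "multi", "cohort"),
                         seed = 1L, spec = NULL, model = NULL, n_bodies = 3) {
  what <- match.arg(what)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (what == "cohort") {
    model <- model %||% cohort_model(seed = seed)
    cohort <- generate_cohort(model)
    csv <- file.path(out_dir, "cohort.csv")
    write_cohort(cohort, csv)
    truth <- file.path(out_dir, "cohort_truth.json")
    jsonlite::write_json(
      cohort[, c("patient_id", ".true_vbmd", ".t_true", ".dxa_inflated")],
      truth, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    return(invisible(c(csv, truth)))
  }
  spec <- spec %||% phantom_spec(seed = seed)
  if (what == "multi") {
    dz <- spec$spacing_mm[1]
    need_mm <- n_bodies * 33 + 2 * 2 * dz
    spec$grid_shape[1] <- max(spec$grid_shape[1], ceiling(need_mm / dz))
    out <- generate_multi_vertebra_phantom(spec, n_bodies)
  } else {
    out <- generate_phantom_volume(spec)
  }
  nii <- file.path(out_dir, paste0(what, ".nii.gz"))
  save_volume(out$volume, nii)
  manifest <- out$manifest
  manifest$masks <- NULL                      # voxel masks stay in-memory only
  mj <- file.path(out_dir, paste0(what, "_manifest.json"))
  jsonlite::write_json(manifest, mj, auto_unbox = TRUE, digits = NA)
  invisible(c(nii, mj))
}
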