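test_that("exclusion reasons are single, prioritized and conserved", {
  roster <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    age = c(60, 61, 62, 63), sex = c("F", "M", "F", "M"),
    has_ldct = c(TRUE, FALSE, TRUE, FALSE),
    has_t12 = c(TRUE, TRUE, FALSE, TRUE),
    dxa_complete = c(TRUE, FALSE, TRUE, TRUE)
  )
  out <- apply_exclusions(roster)
  expect_equal(nrow(out$included), 1)
  expect_equal(nrow(out$excluded), 3)
  # overlapping flags resolve to the highest-priority reason
  expect_equal(as.character(out$excluded$reason[out$excluded$patient_id == "B"]),
               "no_ldct")
  expect_equal(nrow(out$included) + nrow(out$excluded), nrow(roster))

  clean <- tibble::tibble(patient_id = c("X", "Y"), age = c(50, 51),
                          sex = c("F", "M"),
                          spine_dxa_t = -1, fn_dxa_t = -1, th_dxa_t = -1)
  all_in <- apply_exclusions(clean)
  expect_equal(nrow(all_in$included), 2)
  expect_true(all(all_in$tally$n == 0))
})

test_that("cohort summary reproduces direct arithmetic and pooling", {
  two <- tibble::tibble(patient_id = c("a", "b"), age = c(40, 60),
                        sex = c("F", "F"))
  s <- cohort_summary(two, vars = "age")
  expect_equal(s$mean[s$group == "Female"], 50)
  expect_equal(s$sd[s$group == "Female"], 14.14, tolerance = 0.001)

  # pooled mean = count-weighted mean of subgroup means
  expect_equal(round(pool_group_means(c(266, 383), c(55.06, 60.02)), 2), 57.99)

  set.seed(31)
  sim <- tibble::tibble(
    patient_id = sprintf("p%03d", 1:80),
    age = rnorm(80, 58, 11), sex = sample(c("M", "F"), 80, TRUE),
    height_cm = rnorm(80, 165, 8), weight_kg = rnorm(80, 70, 12)
  )
  sim$bmi <- sim$weight_kg / (sim$height_cm / 100)^2
  s2 <- cohort_summary(sim)
  for (v in c("age", "height_cm", "weight_kg")) {
    expect_equal(s2$mean[s2$group == "Total" & s2$variable == v],
                 mean(sim[[v]]), tolerance = 1e-12)
    expect_equal(s2$sd[s2$group == "Total" & s2$variable == v],
                 sd(sim[[v]]), tolerance = 1e-12)
    sub <- s2[s2$variable == v & s2$group != "Total", ]
    expect_equal(pool_group_means(sub$n, sub$mean),
                 s2$mean[s2$group == "Total" & s2$variable == v],
                 tolerance = 1e-12)
  }
})

test_that("age bins are closed on the left with seven fixed labels", {
  expect_equal(as.character(age_bin(c(29, 30, 79.9, 80))),
               c("<30", "30-39", "70-79", "80+"))
  rec <- tibble::tibble(patient_id = c("a", "b"), age = c(34, 85),
                        sex = c("F", "M"), qct_vbmd = c(150, 70))
  strata <- age_stratified_bmd(rec)
  expect_equal(nrow(strata), 14)                    # 7 bins x 2 sexes
  one <- strata[strata$age_bin == "30-39" & strata$sex == "F", ]
  expect_equal(one$n, 1); expect_equal(one$mean, 150); expect_true(is.na(one$sd))
  empty <- strata[strata$age_bin == "40-49" & strata$sex == "F", ]
  expect_equal(empty$n, 0); expect_true(is.na(empty$mean))
})

test_that("precision is the RMS of per-subject SDs", {
  expect_equal(compute_precision(list(s = c(100, 100, 100)))$precision_sd_mgcc, 0)
  one <- compute_precision(list(s = c(98, 102)))
  expect_equal(one$precision_sd_mgcc, 2.828, tolerance = 0.001)
  expect_equal(one$precision_cv_pct, 2.828, tolerance = 0.001)

  set.seed(41)
  df <- tibble::tibble(
    subject_id = rep(sprintf("s%02d", 1:10), each = 3),
    vbmd_mgcc = rnorm(30, rep(runif(10, 80, 160), each = 3), 3)
  )
  got <- compute_precision(df)
  sds <- tapply(df$vbmd_mgcc, df$subject_id, sd)
  expect_equal(got$precision_sd_mgcc, sqrt(mean(sds^2)), tolerance = 1e-12)
  expect_equal(got$precision_cv_pct,
               sqrt(mean(sds^2)) / mean(df$vbmd_mgcc) * 100, tolerance = 1e-12)

  expect_warning(res <- compute_precision(list(a = c(1, 2), b = 3)), "skipped")
  expect_equal(res$n_subjects, 1)
  expect_error(suppressWarnings(compute_precision(list(a = 1, b = 2))),
               "no subject")
})

test_that("pearson_r matches the raw-sums closed form", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 3), 1.0)
  expect_equal(pearson_r(1:10, -(1:10)), -1.0)
  set.seed(51)
  x <- rnorm(25); y <- 0.4 * x + rnorm(25, 0, 0.8)
  expect_equal(pearson_r(x, y), ols_oracle(x, y)$r, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r(1:2, 1:2), ">= 3")
})

test_that("confusion matrix equals a brute-force tally with conserved margins", {
  cats <- bmd_categories()
  same <- confusion_matrix_3x3(cats[c(1, 2, 3, 1)], cats[c(1, 2, 3, 1)])
  expect_equal(sum(diag(same$matrix)), 4)
  expect_equal(same$agreement, 1)

  off <- confusion_matrix_3x3(rep("osteoporosis", 6), rep("normal", 6))
  expect_equal(off$matrix["normal", "osteoporosis"], 6)
  expect_equal(sum(off$matrix), 6)

  set.seed(61)
  pred <- sample(cats, 30, TRUE); ref <- sample(cats, 30, TRUE)
  cm <- confusion_matrix_3x3(pred, ref)
  for (i in cats) for (j in cats) {
    expect_equal(cm$matrix[i, j], sum(ref == i & pred == j))
  }
  expect_equal(sum(cm$matrix), 30)
  expect_equal(sum(cm$pred_rates_pct), 100)
  expect_equal(sum(cm$ref_rates_pct), 100)

  expect_error(confusion_matrix_3x3(cats[1:2], cats[1]), "lengths differ")
  expect_error(confusion_matrix_3x3("severe", "normal"), "unknown")
})
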