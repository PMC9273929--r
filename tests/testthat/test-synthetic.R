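test_that("phantoms are deterministic in the seed and honest about noise", {
  a <- make_phantom(noise = 12, seed = 5)$volume
  b <- make_phantom(noise = 12, seed = 5)$volume
  expect_identical(a$voxels, b$voxels)
  c <- make_phantom(noise = 12, seed = 6)$volume
  expect_false(identical(a$voxels, c$voxels))

  # noise-free construction: trabecular mask mean is the device line exactly
  p <- make_phantom(density = 130)
  z <- p$manifest$t12_center_voxel["z"]
  sl <- p$volume$voxels[z, , ]
  expect_equal(mean(sl[p$manifest$masks$trabecular]),
               p$manifest$compartment_hu$trabecular)
  expect_equal(p$manifest$compartment_hu$trabecular,
               p$manifest$device$hu_per_density_slope * 130 +
                 p$manifest$device$hu_offset)

  # compartment masks are pairwise disjoint
  m <- p$manifest$masks
  pairs <- combn(c("trabecular", "cortical", "fat", "muscle_left",
                   "muscle_right", "lungs"), 2)
  for (k in seq_len(ncol(pairs))) {
    expect_false(any(m[[pairs[1, k]]] & m[[pairs[2, k]]]))
  }
})

test_that("multi-vertebra phantoms stack disjoint bodies or refuse", {
  spec <- phantom_spec(grid_shape = c(44, 120, 120))
  mp <- generate_multi_vertebra_phantom(spec, n_bodies = 3)
  # three disjoint bone runs along z
  corridor_bone <- apply(mp$volume$voxels > 400, 1, any)
  runs <- rle(corridor_bone)
  expect_equal(sum(runs$values), 3)
  expect_equal(nrow(mp$manifest$body_centers), 3)
  expect_error(generate_multi_vertebra_phantom(phantom_spec(), n_bodies = 5),
               "grid too short")
})

test_that("device models are consistent with the configured references", {
  for (i in seq_len(nrow(device_presets()))) {
    d <- device_presets()[i, ]
    dm <- device_model(d$name, d$hu_fat, d$hu_muscle)
    expect_gt(dm$hu_per_density_slope, 0)
    expect_equal(dm$hu_per_density_slope * dm$rho_fat + dm$hu_offset, d$hu_fat)
    expect_equal(dm$hu_per_density_slope * dm$rho_muscle + dm$hu_offset,
                 d$hu_muscle)
  }
})

test_that("cohorts reproduce the configured age-sex density structure", {
  expect_equal(nrow(generate_cohort(cohort_model(n = 0))), 0)

  m <- cohort_model(n = 2000, seed = 3)
  co <- generate_cohort(m)
  expect_identical(co, generate_cohort(m))        # seed reproducibility

  bm <- default_bin_means()
  bins <- age_bin(co$age)
  for (sex in c("F", "M")) {
    for (b in rownames(bm)) {
      sel <- co$sex == sex & bins == b
      if (sum(sel) < 5) next
      se <- m$bin_sd / sqrt(sum(sel))
      expect_lt(abs(mean(co$.true_vbmd[sel]) - bm[b, sex]), 3 * se + 1e-9)
    }
  }
  # progressive decline with age
  f80 <- co$sex == "F" & bins == "80+"
  f30 <- co$sex == "F" & bins == "30-39"
  expect_lt(mean(co$.true_vbmd[f80]), mean(co$.true_vbmd[f30]))

  # inflated records carry higher spine T-scores than their truth implies
  ok <- !is.na(co$spine_dxa_t)
  bias_infl <- mean((co$spine_dxa_t - co$.t_true)[ok & co$.dxa_inflated])
  bias_clean <- mean((co$spine_dxa_t - co$.t_true)[ok & !co$.dxa_inflated])
  expect_gt(bias_infl, bias_clean + 0.5)
})

test_that("a noise-free, inflation-free cohort has concordant DXA and QCT", {
  m <- cohort_model(n = 400, qct_noise_sd = 0, t_noise_sd = 0,
                    inflation_base = 0, inflation_per_year = 0,
                    inflation_max = 0,
                    p_no_ldct = 0, p_no_t12 = 0, p_dxa_incomplete = 0,
                    seed = 9)
  co <- generate_cohort(m)
  dxa <- classify_dxa(composite_dxa_label(co$spine_dxa_t,
                                          pmin(co$fn_dxa_t, co$th_dxa_t))$composite_t)
  qct <- classify_qct(co$qct_vbmd)
  expect_true(all(as.character(dxa) == as.character(qct)))
})

test_that("repeat scans reproduce and respond to noise", {
  spec <- phantom_spec(noise_sd_hu = 0, seed = 2)
  still <- simulate_repeat_scans(spec, n_repeats = 2, reposition_jitter_mm = 0)
  expect_identical(still[[1]]$voxels, still[[2]]$voxels)
  v0 <- vapply(still, function(v) measure_vbmd(v)$vbmd_mgcc, numeric(1))
  expect_equal(compute_precision(list(s = v0))$precision_sd_mgcc, 0)

  noisy_spec <- phantom_spec(noise_sd_hu = 15, seed = 2)
  noisy <- simulate_repeat_scans(noisy_spec, n_repeats = 3,
                                 reposition_jitter_mm = 1)
  again <- simulate_repeat_scans(noisy_spec, n_repeats = 3,
                                 reposition_jitter_mm = 1)
  expect_identical(noisy[[2]]$voxels, again[[2]]$voxels)
  vn <- vapply(noisy, function(v) measure_vbmd(v)$vbmd_mgcc, numeric(1))
  cv_noisy <- compute_precision(list(s = vn))$precision_cv_pct
  expect_true(is.finite(cv_noisy))
  expect_gt(cv_noisy, 0)
})
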