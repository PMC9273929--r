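test_that("ROI statistics: constant ROI, trim contract, brute-force mean", {
  vol <- flat_volume(hu = 40)
  roi <- roi_spec("trabecular", c(3, 16, 16), c(10, 10), 2)
  s <- roi_statistics(vol, roi)
  expect_equal(s$mean_hu, 40)
  expect_equal(s$sd_hu, 0)
  expect_true(s$trimmed)                    # default 5% trim engaged

  # one extreme voxel is removed by a 10% symmetric trim
  vol2 <- flat_volume(hu = 0)
  mask <- roi_mask(vol2, roi)
  idx <- which(mask)
  vol2$voxels[idx[1]] <- 1000
  s2 <- roi_statistics(vol2, roi, trim_fraction = 0.10)
  expect_equal(s2$mean_hu, 0)

  # untrimmed mean equals the direct arithmetic mean
  set.seed(7)
  vol3 <- flat_volume(hu = 0)
  vol3$voxels[] <- rnorm(length(vol3$voxels), 50, 30)
  s3 <- roi_statistics(vol3, roi, trim_fraction = 0)
  expect_equal(s3$mean_hu, mean(vol3$voxels[mask]), tolerance = 1e-12)
  expect_equal(s3$sd_hu, sd(vol3$voxels[mask]), tolerance = 1e-12)
  expect_false(s3$trimmed)

  # small ROIs are flagged unreliable; out-of-volume ROIs are errors
  tiny <- roi_spec("fat", c(3, 16, 16), c(2, 2), 1)
  expect_true(roi_statistics(vol, tiny)$unreliable)
  expect_error(roi_mask(vol, roi_spec("fat", c(3, 2, 2), c(30, 30), 1)),
               "outside volume")
})

test_that("vertebral localization lands within one slice of ground truth", {
  for (dz in c(1, 3, 5)) {
    p <- make_phantom(spacing_mm = c(dz, 2, 2))
    ctr <- locate_vertebral_level(p$volume)
    expect_lte(abs(ctr["z"] - p$manifest$t12_center_voxel["z"]), 1)
    expect_lt(abs(ctr["y"] - p$manifest$t12_center_voxel["y"]) * 2, 4)
    expect_lt(abs(ctr["x"] - p$manifest$t12_center_voxel["x"]) * 2, 4)
  }
})

test_that("multi-vertebra counting selects the requested body from the top", {
  spec <- phantom_spec(grid_shape = c(44, 120, 120))
  mp <- generate_multi_vertebra_phantom(spec, n_bodies = 3)
  truth <- mp$manifest$body_centers
  for (i in 1:3) {
    ctr <- locate_vertebral_level(mp$volume, index = i)
    expect_lte(abs(ctr["z"] - truth$z[truth$body == i]), 1)
  }
  expect_error(locate_vertebral_level(mp$volume, index = 4),
               "level not in field of view")
})

test_that("an all-air volume has no spine", {
  vol <- flat_volume(hu = -1000, dims = c(8, 60, 60))
  expect_error(locate_vertebral_level(vol), "no spine found")
})

test_that("trabecular ROI is exact and clear of the cortical shell", {
  p <- make_phantom(density = 130)
  ctr <- locate_vertebral_level(p$volume)
  roi <- place_trabecular_roi(p$volume, ctr)
  s <- roi_statistics(p$volume, roi, trim_fraction = 0)
  trab_hu <- p$manifest$compartment_hu$trabecular
  expect_equal(s$mean_hu, trab_hu)

  # mask audit: no ROI voxel is a shell voxel
  mask <- roi_mask(p$volume, roi)
  z_mid <- round(ctr["z"])
  expect_false(any(mask[z_mid, , ] & p$manifest$masks$cortical))
  expect_gte(s$n_voxels, 50)

  # a margin wider than the body radius leaves nothing
  expect_error(place_trabecular_roi(p$volume, ctr,
                                    config = list(roi = list(margin_mm = 20))),
               "trabecular ROI degenerate")
})

test_that("a single-slice body yields a valid single-slice ROI", {
  # 5 mm slices with a 9 mm span request -> floor(9/5) = 1 slice
  p <- make_phantom(spacing_mm = c(5, 2, 2))
  ctr <- locate_vertebral_level(p$volume)
  roi <- place_trabecular_roi(p$volume, ctr)
  expect_equal(roi$slice_span, 1L)
  expect_equal(roi_statistics(p$volume, roi, trim_fraction = 0)$mean_hu,
               p$manifest$compartment_hu$trabecular)
})

test_that("tissue ROIs recover pure fat and muscle and never overlap", {
  p <- make_phantom()
  ctr <- locate_vertebral_level(p$volume)
  rois <- place_tissue_rois(p$volume, ctr)
  stats <- lapply(rois, roi_statistics, vol = p$volume, trim_fraction = 0)
  expect_gt(stats$fat$mean_hu, -101); expect_lt(stats$fat$mean_hu, -99)
  for (m in c("muscle_left", "muscle_right")) {
    expect_gt(stats[[m]]$mean_hu, 49); expect_lt(stats[[m]]$mean_hu, 51)
  }
  # left-right symmetry of the symmetric phantom
  expect_lt(abs(stats$muscle_left$mean_hu - stats$muscle_right$mean_hu), 0.5)

  # pairwise disjoint masks, all clear of the cortical shell
  trab <- place_trabecular_roi(p$volume, ctr)
  all_rois <- c(list(trabecular = trab), rois)
  masks <- lapply(all_rois, roi_mask, vol = p$volume)
  nm <- names(masks)
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (i < j) expect_false(any(masks[[i]] & masks[[j]]))
    }
    z_mid <- round(ctr["z"])
    expect_false(any(masks[[i]][z_mid, , ] & p$manifest$masks$cortical))
  }

  # every ROI mean matches its compartment to < 0.5 HU on a noise-free phantom
  truth_hu <- c(trabecular = p$manifest$compartment_hu$trabecular,
                fat = p$manifest$compartment_hu$fat,
                muscle_left = p$manifest$compartment_hu$muscle,
                muscle_right = p$manifest$compartment_hu$muscle)
  for (lbl in names(truth_hu)) {
    s <- roi_statistics(p$volume, all_rois[[lbl]], trim_fraction = 0)
    expect_lt(abs(s$mean_hu - truth_hu[[lbl]]), 0.5)
  }
})

test_that("absent tissue makes the ROI search fail loudly", {
  p <- make_phantom()
  ctr <- locate_vertebral_level(p$volume)
  # a fat window that matches nothing emulates a phantom without a fat layer
  expect_error(
    place_tissue_rois(p$volume, ctr,
                      config = list(roi = list(fat_window = c(-400, -300)))),
    "tissue ROI not found")
})

test_that("ROI sets serialize to a JSON sidecar", {
  p <- make_phantom()
  ctr <- locate_vertebral_level(p$volume)
  rois <- place_tissue_rois(p$volume, ctr)
  path <- file.path(withr::local_tempdir(), "rois.json")
  roi_set_json(rois, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$fat$label, "fat")
  expect_equal(unlist(back$muscle_left$center_voxel),
               unname(rois$muscle_left$center_voxel))
})
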