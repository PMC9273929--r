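test_that("NIfTI round-trip is the identity on voxels, spacing and origin", {
  set.seed(42)
  vox <- array(rnorm(16^3, mean = -200, sd = 400), dim = c(16, 16, 16))
  vox[1, 2, 3] <- 700                       # marked voxel
  vol <- ct_volume(vox, spacing_mm = c(3, 2, 2), origin_mm = c(5, -10, 2.5),
                   device = device_meta("synthetic:rt"), patient_id = "rt01")
  path <- file.path(withr::local_tempdir(), "vol.nii.gz")
  save_volume(vol, path)
  back <- load_volume(path)
  expect_identical(back$voxels, vol$voxels)
  expect_identical(back$spacing_mm, vol$spacing_mm)
  expect_identical(back$origin_mm, vol$origin_mm)
  expect_identical(back$voxels[1, 2, 3], 700)
  expect_identical(back$patient_id, "rt01")
  expect_identical(back$device$manufacturer_model, "synthetic:rt")
})

test_that("writing to a missing directory fails and leaves no partial file", {
  vol <- flat_volume()
  bad <- file.path(tempdir(), "no_such_dir_xyz", "v.nii.gz")
  expect_error(save_volume(vol, bad), "directory")
  expect_false(file.exists(bad))
})

test_that("DICOM series load rescales to HU and sorts slices by z position", {
  dir <- withr::local_tempdir()
  vox <- array(0, dim = c(2, 8, 8))
  vox[1, , ] <- 0                           # HU 0 -> stored 1024 at (1, -1024)
  vox[2, , ] <- 100
  vol <- ct_volume(vox, spacing_mm = c(3, 1, 1), origin_mm = c(5, 0, 0),
                   patient_id = "dcm01")
  write_dicom <- getFromNamespace("write_dicom_series", "plqct")
  write_dicom(vol, dir, rescale_slope = 1, rescale_intercept = -1024)
  back <- load_volume(dir)
  expect_equal(back$voxels, vox)
  expect_equal(back$spacing_mm, c(3, 1, 1))
  expect_identical(back$patient_id, "dcm01")

  # z-sort contract: write slices at z = 10 then z = 5 under one series UID,
  # with filenames in the "wrong" order
  dir2 <- withr::local_tempdir()
  v10 <- ct_volume(array(111, dim = c(1, 4, 4)), c(3, 1, 1), c(10, 0, 0))
  v5 <- ct_volume(array(55, dim = c(1, 4, 4)), c(3, 1, 1), c(5, 0, 0))
  write_dicom(v10, dir2)
  file.rename(file.path(dir2, "slice_0001.dcm"), file.path(dir2, "a.dcm"))
  write_dicom(v5, dir2)
  file.rename(file.path(dir2, "slice_0001.dcm"), file.path(dir2, "b.dcm"))
  back2 <- load_volume(dir2)
  expect_equal(back2$voxels[1, 1, 1], 55)   # z = 5 first
  expect_equal(back2$voxels[2, 1, 1], 111)
  expect_equal(back2$origin_mm[1], 5)
})

test_that("non-CT, multi-series and irregularly spaced DICOM input are rejected", {
  write_dicom <- getFromNamespace("write_dicom_series", "plqct")
  one_slice <- function(z) {
    ct_volume(array(0, dim = c(1, 4, 4)), c(3, 1, 1), c(z, 0, 0))
  }
  keep_as <- function(dir, name) {
    file.rename(file.path(dir, "slice_0001.dcm"), file.path(dir, name))
  }

  d1 <- withr::local_tempdir()
  write_dicom(one_slice(0), d1, modality = "MR")
  expect_error(load_volume(d1), "wrong modality")

  d2 <- withr::local_tempdir()
  write_dicom(one_slice(0), d2, series_uid = "1.2.3.1"); keep_as(d2, "s1.dcm")
  write_dicom(one_slice(3), d2, series_uid = "1.2.3.2"); keep_as(d2, "s2.dcm")
  expect_error(load_volume(d2), "ambiguous input")

  d3 <- withr::local_tempdir()
  write_dicom(one_slice(0), d3); keep_as(d3, "s1.dcm")
  write_dicom(one_slice(3), d3); keep_as(d3, "s2.dcm")
  write_dicom(one_slice(7), d3); keep_as(d3, "s3.dcm")   # gap 3 then 4 (> 10%)
  expect_error(load_volume(d3), "irregular geometry")
})

test_that("cohort CSV loads typed records with explicit absences", {
  path <- write_cohort_fixture(c(
    "patient_id,age,sex,height_cm,weight_kg,spine_dxa_t,fn_dxa_t,th_dxa_t,qct_vbmd",
    "P1,64,F,160,62,-2.1,-1.8,-1.9,95.2",
    "P2,55,M,172,80,,-0.5,-0.4,130.0",
    "P3,71,F,158,66,-2.9,-2.2,-2.5,70.1"
  ))
  tbl <- load_cohort(path)
  expect_equal(nrow(tbl), 3)
  expect_equal(tbl$age, c(64, 55, 71))
  expect_true(is.na(tbl$spine_dxa_t[2]))
  expect_equal(tbl$dxa_complete, c(TRUE, FALSE, TRUE))  # empty cell flags P2
  expect_equal(tbl$bmi, tbl$weight_kg / (tbl$height_cm / 100)^2, tolerance = 1e-12)
})

test_that("cohort schema violations are errors, not coercions", {
  bad_sex <- write_cohort_fixture(c("patient_id,age,sex", "P1,50,X"))
  expect_error(load_cohort(bad_sex), "sex")
  unknown <- write_cohort_fixture(c("patient_id,age,sex,shoe_size", "P1,50,M,44"))
  expect_error(load_cohort(unknown), "unknown cohort column")
  bad_num <- write_cohort_fixture(c("patient_id,age,sex,qct_vbmd", "P1,50,M,high"))
  expect_error(load_cohort(bad_num), "unparseable")
})
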