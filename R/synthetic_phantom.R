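# Digital chest-CT phantom at the T12 level, with recorded ground truth.
#
# The phantom is deliberately schematic: concentric axial anatomy (air
# background, two lung fields, soft-tissue thorax, subcutaneous fat band,
# two paraspinal muscle ellipses, a vertebral-body cylinder with cortical
# shell and trabecular core) plus a per-device linear HU response and
# additive Gaussian noise. It provides exactly what the ROI and calibration
# logic needs to be scored against known truth; it does not model
# reconstruction physics.

#' Linear HU response of a simulated scanner
#'
#' A device maps equivalent density (mg/cc) to HU as
#' `HU = hu_per_density_slope * density + hu_offset`. The fat and muscle HU
#' rendered by the device are derived from the same line at the configured
#' reference densities, so a pipeline calibrated with matching references
#' recovers the true density exactly on noise-free data — the property that
#' makes phantom-less calibration device-invariant.
#'
#' @param name device label (reported as `synthetic:<name>` in metadata
#'   unless it already contains a colon).
#' @param hu_fat,hu_muscle HU this device renders for the reference tissues.
#' @param rho_fat,rho_muscle the reference equivalent densities (mg/cc)
#'   those HU correspond to (defaults match [plqct_config()]).
#' @return an object of class `device_model` with fields
#'   `hu_per_density_slope` and `hu_offset` derived from the two anchors.
#' @export
#' @examples
#' device_model("A")$hu_per_density_slope  # 5/3 for the default anchors
device_model <- function(name = "A", hu_fat = -100, hu_muscle = 50,
                         rho_fat = -50, rho_muscle = 40) {
  if (hu_muscle <= hu_fat) abort("hu_muscle must exceed hu_fat")
  if (rho_muscle <= rho_fat) abort("rho_muscle must exceed rho_fat")
  slope <- (hu_muscle - hu_fat) / (rho_muscle - rho_fat)
  structure(
    list(name = name,
         hu_per_density_slope = slope,
         hu_offset = hu_fat - slope * rho_fat,
         hu_fat = hu_fat, hu_muscle = hu_muscle,
         rho_fat = rho_fat, rho_muscle = rho_muscle),
    class = "device_model"
  )
}

density_to_hu <- function(dev, density) {
  dev$hu_per_density_slope * density + dev$hu_offset
}

#' Simulated scanner presets
#'
#' Four low-dose chest protocols with distinct linear HU responses and slice
#' thicknesses spanning the 1-5 mm range seen across clinical scanners. The
#' HU responses are synthetic choices; the acquisition parameters (120 kVp,
#' the mA and slice-thickness combinations) mirror typical screening
#' protocols.
#'
#' @return a tibble: `name, kVp, mA, slice_thickness_mm, hu_fat, hu_muscle`.
#' @export
device_presets <- function() {
  tibble(
    name = c("NeuViz epoch", "Philips iCT 256", "GE Revolution CT", "SCENARIA"),
    kVp = 120,
    mA = c(345, 225, 254, 254),
    slice_thickness_mm = c(3, 1, 5, 5),
    hu_fat = c(-100, -95, -105, -98),
    hu_muscle = c(50, 55, 45, 58)
  )
}

#' Phantom specification
#'
#' @param true_density_mgcc true trabecular equivalent density (mg/cc).
#' @param spacing_mm voxel size `(z, y, x)` in mm.
#' @param grid_shape `(nz, ny, nx)`; by default derived so the volume covers
#'   roughly 72 x 240 x 240 mm.
#' @param device a [device_model()].
#' @param noise_sd_hu SD of additive Gaussian HU noise (0 = noise-free).
#' @param seed RNG seed; a fixed seed gives a bit-identical volume.
#' @param patient_id carried into the volume metadata.
#' @param offset_mm in-plane `(y, x)` translation of the whole anatomy
#'   relative to the grid center (used by [simulate_repeat_scans()] to model
#'   repositioning between acquisitions).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(true_density_mgcc = 130, spacing_mm = c(3, 2, 2),
                         grid_shape = NULL, device = device_model(),
                         noise_sd_hu = 0, seed = 1L,
                         patient_id = "phantom", offset_mm = c(0, 0)) {
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0)) {
    abort("spacing_mm must be three positive numbers (z, y, x)")
  }
  if (is.null(grid_shape)) {
    grid_shape <- c(round(72 / spacing_mm[1]),
                    round(240 / spacing_mm[2]),
                    round(240 / spacing_mm[3]))
  }
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 1)) {
    abort("grid_shape must be three positive integers (nz, ny, nx)")
  }
  if (!is.finite(true_density_mgcc)) abort("true_density_mgcc must be finite")
  if (!is.finite(noise_sd_hu) || noise_sd_hu < 0) abort("noise_sd_hu must be >= 0")
  stopifnot(inherits(device, "device_model"))
  offset_mm <- as.numeric(offset_mm)
  if (length(offset_mm) != 2 || any(!is.finite(offset_mm))) {
    abort("offset_mm must be two finite numbers (y, x)")
  }
  structure(
    list(true_density_mgcc = true_density_mgcc,
         spacing_mm = spacing_mm, grid_shape = grid_shape,
         device = device, noise_sd_hu = noise_sd_hu,
         seed = as.integer(seed), patient_id = patient_id,
         offset_mm = offset_mm),
    class = "phantom_spec"
  )
}

# Fixed nominal HU of the non-calibrated compartments.
PHANTOM_HU <- list(air = -1000, lung = -800, soft = 0, cortical = 800)

# Anatomy in mm, relative to the in-plane center (Cy, Cx).
PHANTOM_GEOM <- list(
  body_semi = c(95, 110),          # soft-tissue thorax (y, x)
  inner_shift = -4,                # fat-band inner boundary: anterior shift
  inner_semi = c(86, 102),
  lung_center = c(-35, 45),        # (y, +/-x)
  lung_semi = c(40, 32),
  vert_center_y = 48,
  vert_outer_r = 16,
  vert_shell = 3,
  muscle_center = c(64, 30),       # (y, +/-x)
  muscle_semi = c(12, 16),
  body_z_mm = c(24, 48),           # single-body craniocaudal extent
  body_height_mm = 24,
  disc_gap_mm = 9
)

ellipse_mask <- function(ymm, xmm, cy, cx, a, b) {
  outer(((ymm - cy) / a)^2, ((xmm - cx) / b)^2, `+`) <= 1
}

# 2-D compartment masks shared by all slices.
phantom_plane_masks <- function(spec) {
  g <- PHANTOM_GEOM
  d <- spec$grid_shape
  ymm <- axis_mm(d[2], spec$spacing_mm[2])
  xmm <- axis_mm(d[3], spec$spacing_mm[3])
  Cy <- d[2] * spec$spacing_mm[2] / 2 + spec$offset_mm[1]
  Cx <- d[3] * spec$spacing_mm[3] / 2 + spec$offset_mm[2]

  body <- ellipse_mask(ymm, xmm, Cy, Cx, g$body_semi[1], g$body_semi[2])
  inner <- ellipse_mask(ymm, xmm, Cy + g$inner_shift, Cx,
                        g$inner_semi[1], g$inner_semi[2])
  lungs <- ellipse_mask(ymm, xmm, Cy + g$lung_center[1], Cx - g$lung_center[2],
                        g$lung_semi[1], g$lung_semi[2]) |
    ellipse_mask(ymm, xmm, Cy + g$lung_center[1], Cx + g$lung_center[2],
                 g$lung_semi[1], g$lung_semi[2])
  muscle_left <- ellipse_mask(ymm, xmm, Cy + g$muscle_center[1],
                              Cx - g$muscle_center[2],
                              g$muscle_semi[1], g$muscle_semi[2])
  muscle_right <- ellipse_mask(ymm, xmm, Cy + g$muscle_center[1],
                               Cx + g$muscle_center[2],
                               g$muscle_semi[1], g$muscle_semi[2])
  vert_outer <- ellipse_mask(ymm, xmm, Cy + g$vert_center_y, Cx,
                             g$vert_outer_r, g$vert_outer_r)
  core_r <- g$vert_outer_r - g$vert_shell
  trab <- ellipse_mask(ymm, xmm, Cy + g$vert_center_y, Cx, core_r, core_r)
  list(
    body = body, fat = body & !inner, lungs = lungs,
    muscle_left = muscle_left, muscle_right = muscle_right,
    cortical = vert_outer & !trab, trabecular = trab,
    center_mm = c(Cy + g$vert_center_y, Cx),
    center_voxel = c(Cy + g$vert_center_y, Cx) / spec$spacing_mm[2:3] + 0.5
  )
}

# Paint one axial slice. `vertebra` toggles the vertebral body.
phantom_slice <- function(masks, spec, vertebra) {
  dev <- spec$device
  sl <- matrix(PHANTOM_HU$air, nrow(masks$body), ncol(masks$body))
  sl[masks$body] <- PHANTOM_HU$soft
  sl[masks$fat] <- dev$hu_fat
  sl[masks$lungs] <- PHANTOM_HU$lung
  sl[masks$muscle_left | masks$muscle_right] <- dev$hu_muscle
  if (vertebra) {
    sl[masks$cortical] <- PHANTOM_HU$cortical
    sl[masks$trabecular] <- density_to_hu(dev, spec$true_density_mgcc)
  }
  sl
}

assemble_phantom <- function(spec, vert_slices) {
  d <- spec$grid_shape
  masks <- phantom_plane_masks(spec)
  with_vert <- phantom_slice(masks, spec, vertebra = TRUE)
  without <- phantom_slice(masks, spec, vertebra = FALSE)
  vox <- array(0, dim = d)
  for (z in seq_len(d[1])) {
    vox[z, , ] <- if (z %in% vert_slices) with_vert else without
  }
  if (spec$noise_sd_hu > 0) {
    vox <- vox + withr::with_seed(
      spec$seed, array(rnorm(prod(d), sd = spec$noise_sd_hu), dim = d))
  }
  dev_meta <- device_meta(
    manufacturer_model = if (grepl(":", spec$device$name)) spec$device$name
                         else paste0("synthetic:", spec$device$name),
    slice_thickness_mm = spec$spacing_mm[1]
  )
  list(
    volume = ct_volume(vox, spacing_mm = spec$spacing_mm,
                       device = dev_meta, patient_id = spec$patient_id),
    masks = masks
  )
}

zrange_to_slices <- function(zr, dz, nz) {
  zc <- axis_mm(nz, dz)
  which(zc >= zr[1] & zc <= zr[2])
}

#' Generate a single-vertebra chest phantom
#'
#' Renders the phantom described by `spec` and returns the volume together
#' with a ground-truth manifest sufficient to score every pipeline stage:
#' the true density, the device line, the per-compartment nominal HU, the
#' true mid-body center, and the 2-D compartment masks.
#'
#' @param spec a [phantom_spec()].
#' @return a list: `volume` (a [ct_volume()]) and `manifest` (a list; see
#'   Details in the package vignette).
#' @export
generate_phantom_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- PHANTOM_GEOM
  d <- spec$grid_shape
  dz <- spec$spacing_mm[1]
  vert_slices <- zrange_to_slices(g$body_z_mm, dz, d[1])
  if (length(vert_slices) == 0 || max(g$body_z_mm) > d[1] * dz) {
    abort("vertebral body does not fit the grid")
  }
  built <- assemble_phantom(spec, vert_slices)
  check_plane_fit(built$masks)
  dev <- spec$device
  manifest <- list(
    true_density_mgcc = spec$true_density_mgcc,
    device = unclass(dev),
    compartment_hu = c(PHANTOM_HU,
                       list(fat = dev$hu_fat, muscle = dev$hu_muscle,
                            trabecular = density_to_hu(dev, spec$true_density_mgcc))),
    t12_center_voxel = c(z = floor(median(vert_slices)),
                         y = built$masks$center_voxel[1],
                         x = built$masks$center_voxel[2]),
    vertebra_slices = vert_slices,
    spacing_mm = spec$spacing_mm,
    noise_sd_hu = spec$noise_sd_hu,
    seed = spec$seed,
    masks = built$masks[c("trabecular", "cortical", "fat",
                          "muscle_left", "muscle_right", "lungs", "body")]
  )
  list(volume = built$volume, manifest = manifest)
}

check_plane_fit <- function(masks) {
  edge <- rbind(masks$body[1, , drop = FALSE], masks$body[nrow(masks$body), , drop = FALSE])
  if (any(edge) || any(masks$body[, 1]) || any(masks$body[, ncol(masks$body)])) {
    abort("compartments geometrically impossible for grid: body touches the border")
  }
}

#' Generate a stacked multi-vertebra phantom
#'
#' Stacks `n_bodies` vertebral bodies separated by disc gaps (soft tissue),
#' most cranial body first in the manifest. Used to exercise level counting.
#'
#' @param spec a [phantom_spec()]; its grid must be tall enough.
#' @param n_bodies number of vertebral bodies (>= 1).
#' @return a list: `volume`, `manifest` (with `body_centers`, a tibble of
#'   per-body center voxels ordered cranial to caudal).
#' @export
generate_multi_vertebra_phantom <- function(spec, n_bodies = 3) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_bodies < 1) abort("n_bodies must be >= 1")
  g <- PHANTOM_GEOM
  d <- spec$grid_shape
  dz <- spec$spacing_mm[1]
  zmax <- d[1] * dz
  margin <- 2 * dz
  need <- n_bodies * g$body_height_mm + (n_bodies - 1) * g$disc_gap_mm + 2 * margin
  if (need > zmax) {
    abort(paste0("grid too short for ", n_bodies, " bodies: need ", need,
                 " mm, have ", zmax, " mm"))
  }
  tops <- zmax - margin - (seq_len(n_bodies) - 1) * (g$body_height_mm + g$disc_gap_mm)
  ranges <- lapply(tops, function(t) c(t - g$body_height_mm, t))
  slices <- lapply(ranges, zrange_to_slices, dz = dz, nz = d[1])
  built <- assemble_phantom(spec, unlist(slices))
  centers <- tibble(
    body = seq_len(n_bodies),
    z = vapply(slices, function(s) floor(median(s)), numeric(1)),
    y = built$masks$center_voxel[1],
    x = built$masks$center_voxel[2]
  )
  manifest <- list(
    true_density_mgcc = spec$true_density_mgcc,
    device = unclass(spec$device),
    body_centers = centers,
    spacing_mm = spec$spacing_mm,
    seed = spec$seed
  )
  list(volume = built$volume, manifest = manifest)
}

#' Simulate repeat acquisitions of one subject
#'
#' Re-renders the same phantom `n_repeats` times with fresh noise and a
#' small random in-plane repositioning of the whole anatomy, emulating the
#' re-scan protocol behind short-term precision (RMS-SD / CV%) estimates.
#'
#' @param spec a [phantom_spec()].
#' @param n_repeats number of acquisitions (>= 2).
#' @param reposition_jitter_mm SD of the in-plane translation (0 = none).
#' @return a list of [ct_volume()] objects; the applied `(dy, dx)` offsets
#'   are attached as attribute `"offsets_mm"`.
#' @export
simulate_repeat_scans <- function(spec, n_repeats = 3, reposition_jitter_mm = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_repeats < 2) abort("n_repeats must be >= 2")
  offsets <- withr::with_seed(
    spec$seed,
    matrix(rnorm(2 * n_repeats, sd = reposition_jitter_mm), ncol = 2))
  vols <- lapply(seq_len(n_repeats), function(i) {
    sp <- spec
    sp$seed <- spec$seed + 1000L + i          # fresh noise per repeat
    sp$offset_mm <- spec$offset_mm + offsets[i, ]
    generate_phantom_volume(sp)$volume
  })
  attr(vols, "offsets_mm") <- offsets
  vols
}
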