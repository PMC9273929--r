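# ROI selection: vertebral level localization and parametric elliptical ROIs
# over trabecular bone, paraspinal muscle and subcutaneous fat.

ROI_LABELS <- c("trabecular", "muscle_left", "muscle_right", "fat")

#' Parametric elliptical ROI
#'
#' ROIs are axis-aligned ellipses in the axial plane, replicated over a span
#' of contiguous slices. Geometry is stored in physical units (mm semi-axes)
#' so ROIs are volumetrically comparable across slice thicknesses; centers
#' are 1-based voxel coordinates (fractional in-plane centers are allowed).
#'
#' @param label one of `"trabecular"`, `"muscle_left"`, `"muscle_right"`,
#'   `"fat"`.
#' @param center_voxel numeric (z, y, x), 1-based.
#' @param semi_axes_mm numeric (a, b): semi-axis along rows (anteroposterior)
#'   and along columns (lateral), both > 0.
#' @param slice_span integer >= 1, number of axial slices covered.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(label, center_voxel, semi_axes_mm, slice_span = 1L) {
  label <- match.arg(label, ROI_LABELS)
  center_voxel <- as.numeric(center_voxel)
  semi_axes_mm <- as.numeric(semi_axes_mm)
  if (length(center_voxel) != 3 || any(!is.finite(center_voxel))) {
    abort("center_voxel must be finite (z, y, x)")
  }
  if (length(semi_axes_mm) != 2 || any(semi_axes_mm <= 0)) {
    abort("semi_axes_mm must be two positive numbers")
  }
  slice_span <- as.integer(slice_span)
  if (is.na(slice_span) || slice_span < 1) abort("slice_span must be >= 1")
  structure(
    list(label = label, center_voxel = center_voxel,
         semi_axes_mm = semi_axes_mm, slice_span = slice_span,
         shape = "ellipse"),
    class = "roi_spec"
  )
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf(
    "<roi_spec> %s: center (z=%g, y=%.1f, x=%.1f), semi-axes %.1f x %.1f mm, %d slice(s)\n",
    x$label, x$center_voxel[1], x$center_voxel[2], x$center_voxel[3],
    x$semi_axes_mm[1], x$semi_axes_mm[2], x$slice_span))
  invisible(x)
}

roi_slices <- function(roi) {
  z0 <- round(roi$center_voxel[1]) - (roi$slice_span - 1L) %/% 2L
  seq.int(z0, length.out = roi$slice_span)
}

# In-plane logical mask of the ROI ellipse for one slice.
roi_plane_mask <- function(roi, ny, nx, dy, dx) {
  cy <- roi$center_voxel[2]; cx <- roi$center_voxel[3]
  a <- roi$semi_axes_mm[1]; b <- roi$semi_axes_mm[2]
  ry <- ((seq_len(ny) - cy) * dy) / a
  rx <- ((seq_len(nx) - cx) * dx) / b
  outer(ry^2, rx^2, `+`) <= 1
}

#' Full-volume logical mask of an ROI
#'
#' @param vol a [ct_volume()].
#' @param roi a [roi_spec()].
#' @return a logical array with the dimensions of `vol$voxels`.
#' @export
roi_mask <- function(vol, roi) {
  d <- dim(vol$voxels)
  zs <- roi_slices(roi)
  if (any(zs < 1 | zs > d[1])) abort("ROI outside volume bounds (z)")
  cy <- roi$center_voxel[2]; cx <- roi$center_voxel[3]
  dy <- vol$spacing_mm[2]; dx <- vol$spacing_mm[3]
  if ((cy - 1) * dy < roi$semi_axes_mm[1] ||
      (d[2] - cy) * dy < roi$semi_axes_mm[1] ||
      (cx - 1) * dx < roi$semi_axes_mm[2] ||
      (d[3] - cx) * dx < roi$semi_axes_mm[2]) {
    abort("ROI outside volume bounds (in-plane)")
  }
  plane <- roi_plane_mask(roi, d[2], d[3], dy, dx)
  mask <- array(FALSE, dim = d)
  for (z in zs) mask[z, , ] <- plane
  mask
}

roi_values <- function(vol, roi) vol$voxels[roi_mask(vol, roi)]

#' HU statistics over an ROI
#'
#' Computes the trimmed mean and SD of HU over the ROI voxels: a fraction
#' `trim_fraction` of the most extreme values is removed from each tail
#' (`floor(n * trim_fraction)` voxels per side) before the mean and sample SD
#' are taken, which keeps single streak or vessel voxels from biasing the
#' tissue estimate. ROIs below `min_voxels` voxels are flagged unreliable but
#' still reported.
#'
#' @param vol a [ct_volume()].
#' @param roi a [roi_spec()].
#' @param trim_fraction fraction trimmed per tail (default 0.05).
#' @param min_voxels reliability floor on the untrimmed voxel count.
#' @return a one-row tibble: `label, mean_hu, sd_hu, n_voxels, trimmed,
#'   unreliable`.
#' @export
roi_statistics <- function(vol, roi, trim_fraction = 0.05, min_voxels = 50) {
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    abort("trim_fraction must be in [0, 0.5)")
  }
  v <- roi_values(vol, roi)
  n <- length(v)
  if (n == 0) abort("empty ROI")
  k <- floor(n * trim_fraction)
  kept <- if (k > 0) sort(v)[(k + 1):(n - k)] else v
  s <- if (length(kept) > 1) sd(kept) else 0
  tibble(
    label = roi$label,
    mean_hu = mean(kept),
    sd_hu = s,
    n_voxels = n,
    trimmed = k > 0,
    unreliable = n < min_voxels
  )
}

# Posterior-midline corridor mask (2-D) used when searching for the spine.
spine_corridor <- function(ny, nx, dy, dx, halfwidth_mm) {
  cx_mm <- nx * dx / 2
  cy_mm <- ny * dy / 2
  x_ok <- abs(axis_mm(nx, dx) - cx_mm) <= halfwidth_mm
  y_ok <- axis_mm(ny, dy) >= cy_mm
  outer(y_ok, x_ok, `&`)
}

#' Locate a vertebral level
#'
#' Finds the mid-body voxel of the requested vertebral body. Bone is
#' thresholded (`roi$bone_hu_threshold`, default 200 HU) inside a posterior
#' midline corridor; contiguous runs of slices with sufficient bone area are
#' treated as vertebral bodies separated by disc gaps; bodies are counted
#' caudally starting from the most cranial fully-imaged body (slice index
#' increases toward the head). The mid-body slice is the median slice of the
#' selected run and the in-plane center is the bone centroid on that slice.
#'
#' @param vol a [ct_volume()].
#' @param level vertebral label (cosmetic; carried into messages).
#' @param index which body, counted caudally from the most cranial
#'   fully-imaged one (default 1: in a phantom or a cropped chest volume the
#'   first complete body is the measured level).
#' @param config a [plqct_config()] (or named overrides).
#' @return numeric `c(z, y, x)` voxel coordinates (y, x may be fractional).
#' @export
locate_vertebral_level <- function(vol, level = "T12", index = 1L,
                                   config = NULL) {
  cfg <- as_config(config)
  d <- dim(vol$voxels)
  dy <- vol$spacing_mm[2]; dx <- vol$spacing_mm[3]
  corridor <- spine_corridor(d[2], d[3], dy, dx, cfg$roi$corridor_halfwidth_mm)
  bone_thr <- cfg$roi$bone_hu_threshold
  area <- vapply(seq_len(d[1]), function(z) {
    sum(vol$voxels[z, , ] > bone_thr & corridor) * dy * dx
  }, numeric(1))
  present <- area >= cfg$roi$min_bone_area_mm2
  if (!any(present)) abort("no spine found")

  r <- rle(present)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # most cranial first (slice index increases toward the head)
  runs <- runs[order(-runs$end), , drop = FALSE]
  complete <- runs$end < d[1]          # touching the top slice => partially imaged
  runs <- runs[complete, , drop = FALSE]
  if (nrow(runs) == 0 || index > nrow(runs)) {
    abort(paste0("level not in field of view: ", level,
                 " (body #", index, " of ", nrow(runs), " complete bodies)"))
  }
  run <- runs[index, ]
  z_mid <- floor(median(seq.int(run$start, run$end)))
  sl <- vol$voxels[z_mid, , ] > bone_thr & corridor
  idx <- which(sl, arr.ind = TRUE)
  c(z = z_mid, y = mean(idx[, 1]), x = mean(idx[, 2]))
}

#' Place the trabecular ROI
#'
#' Grows a circular ROI from the mid-body center and keeps it clear of the
#' cortical shell: the radius is the in-plane distance from the center to the
#' nearest cortical-level voxel (`roi$cortical_hu_threshold`, default 400 HU)
#' minus a safety margin (`roi$margin_mm`, default 3 mm), evaluated over the
#' whole slice span. The span is `floor(slice_span_mm / dz)` slices (minimum
#' 1) centered on the mid-body slice.
#'
#' @param vol a [ct_volume()].
#' @param center_voxel `c(z, y, x)` from [locate_vertebral_level()].
#' @param config a [plqct_config()] (or named overrides).
#' @return a [roi_spec()] with label `"trabecular"`.
#' @export
place_trabecular_roi <- function(vol, center_voxel, config = NULL) {
  cfg <- as_config(config)
  d <- dim(vol$voxels)
  dz <- vol$spacing_mm[1]; dy <- vol$spacing_mm[2]; dx <- vol$spacing_mm[3]
  span <- max(1L, as.integer(floor(cfg$roi$slice_span_mm / dz)))
  roi0 <- roi_spec("trabecular", center_voxel, c(1, 1), span)
  zs <- roi_slices(roi0)
  if (any(zs < 1 | zs > d[1])) abort("trabecular ROI degenerate: span exceeds volume")

  cy <- center_voxel[2]; cx <- center_voxel[3]
  min_dist <- Inf
  for (z in zs) {
    idx <- which(vol$voxels[z, , ] > cfg$roi$cortical_hu_threshold, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      dist <- sqrt(((idx[, 1] - cy) * dy)^2 + ((idx[, 2] - cx) * dx)^2)
      min_dist <- min(min_dist, min(dist))
    }
  }
  max_r <- 25                                  # sanity cap, mm
  r <- min(min_dist - cfg$roi$margin_mm, max_r)
  if (!is.finite(r) || r <= 0) abort("trabecular ROI degenerate: margin leaves no voxels")
  roi <- roi_spec("trabecular", center_voxel, c(r, r), span)
  n <- sum(roi_mask(vol, roi))
  if (n < cfg$roi$min_roi_voxels) {
    abort(paste0("trabecular ROI degenerate: only ", n, " voxels"))
  }
  roi
}

ebi <- function(x) EBImage::imageData(x)

# Largest inscribed axis-aligned ellipse of a 2-D component, grown from the
# distance-transform peak in 0.5 mm steps.
inscribed_ellipse <- function(mask, dy, dx) {
  dm <- ebi(EBImage::distmap(mask * 1))
  peak <- which.max(dm)
  c0 <- arrayInd(peak, dim(mask))
  r0 <- max((dm[peak] - 0.5) * min(dy, dx), 0.5)
  fits <- function(a, b) {
    ry <- ((seq_len(nrow(mask)) - c0[1]) * dy) / a
    rx <- ((seq_len(ncol(mask)) - c0[2]) * dx) / b
    inside <- outer(ry^2, rx^2, `+`) <= 1
    all(mask[inside])
  }
  a <- b <- r0
  step <- 0.5
  repeat {
    grew <- FALSE
    if (a + step < 80 && fits(a + step, b)) { a <- a + step; grew <- TRUE }
    if (b + step < 80 && fits(a, b + step)) { b <- b + step; grew <- TRUE }
    if (!grew) break
  }
  list(center = c0, semi_axes = c(a, b))
}

# Candidate tissue mask: inside the HU window on every slice of the span.
window_mask_span <- function(vol, zs, window) {
  d <- dim(vol$voxels)
  m <- matrix(TRUE, d[2], d[3])
  for (z in zs) {
    sl <- vol$voxels[z, , ]
    m <- m & (sl >= window[1] & sl <= window[2])
  }
  m
}

#' Place the fat and paraspinal muscle ROIs
#'
#' Candidate masks come from HU windows (fat [-190, -30]; muscle [10, 100],
#' both configurable), restricted anatomically: muscle to two paraspinal
#' regions posterior to the vertebral centroid and within
#' `roi$muscle_lateral_mm` of the midline; fat to the subcutaneous band
#' within `roi$subcut_depth_mm` of the skin surface. Each region's largest
#' morphologically-opened connected component receives its inscribed ellipse
#' scaled by `roi$inscribe_scale` (default 0.8).
#'
#' @param vol a [ct_volume()].
#' @param center_voxel `c(z, y, x)` from [locate_vertebral_level()].
#' @param config a [plqct_config()] (or named overrides).
#' @return a named list of [roi_spec()]: `fat`, `muscle_left`, `muscle_right`.
#' @export
place_tissue_rois <- function(vol, center_voxel, config = NULL) {
  cfg <- as_config(config)
  d <- dim(vol$voxels)
  dz <- vol$spacing_mm[1]; dy <- vol$spacing_mm[2]; dx <- vol$spacing_mm[3]
  span <- max(1L, as.integer(floor(cfg$roi$slice_span_mm / dz)))
  zs <- roi_slices(roi_spec("fat", center_voxel, c(1, 1), span))
  zs <- zs[zs >= 1 & zs <= d[1]]
  z_mid <- round(center_voxel[1])
  cy <- center_voxel[2]; cx <- center_voxel[3]

  sl <- vol$voxels[z_mid, , ]
  # air connected to the image border separates "outside" from lung
  airish <- sl < -400
  lab <- ebi(EBImage::bwlabel(airish * 1))
  border_labels <- setdiff(unique(c(lab[1, ], lab[nrow(lab), ],
                                    lab[, 1], lab[, ncol(lab)])), 0)
  outside <- lab %in% border_labels
  dim(outside) <- dim(lab)
  depth <- ebi(EBImage::distmap((!outside) * 1)) * min(dy, dx)

  brush_px <- max(3L, round(3 / min(dy, dx)) * 2L + 1L)
  brush <- EBImage::makeBrush(brush_px, "disc")
  min_area_px <- cfg$roi$min_tissue_area_mm2 / (dy * dx)

  largest_component <- function(cand) {
    cand <- ebi(EBImage::opening(cand * 1, brush)) > 0
    lab <- ebi(EBImage::bwlabel(cand * 1))
    if (max(lab) == 0) return(NULL)
    sizes <- tabulate(lab[lab > 0])
    best <- which.max(sizes)
    if (sizes[best] < min_area_px) return(NULL)
    lab == best
  }

  place_in <- function(cand, label) {
    comp <- largest_component(cand)
    if (is.null(comp)) abort(paste0("tissue ROI not found: ", label))
    ell <- inscribed_ellipse(comp, dy, dx)
    roi_spec(label, c(z_mid, ell$center[1], ell$center[2]),
             ell$semi_axes * cfg$roi$inscribe_scale, span)
  }

  ymm <- axis_mm(d[2], dy); xmm <- axis_mm(d[3], dx)
  cy_mm <- cy * dy; cx_mm <- cx * dx
  post <- outer(ymm > cy_mm, rep(TRUE, d[3]), `&`)
  lat <- outer(rep(TRUE, d[2]), abs(xmm - cx_mm) <= cfg$roi$muscle_lateral_mm, `&`)
  left <- outer(rep(TRUE, d[2]), xmm < cx_mm, `&`)

  muscle_w <- window_mask_span(vol, zs, cfg$roi$muscle_window)
  fat_w <- window_mask_span(vol, zs, cfg$roi$fat_window)

  fat <- place_in(fat_w & !outside & depth > 0 & depth <= cfg$roi$subcut_depth_mm,
                  "fat")
  muscle_left <- place_in(muscle_w & post & lat & left, "muscle_left")
  muscle_right <- place_in(muscle_w & post & lat & !left, "muscle_right")
  list(fat = fat, muscle_left = muscle_left, muscle_right = muscle_right)
}

#' Serialize a set of ROIs to JSON
#'
#' Writes label, center, semi-axes and slice span for each ROI to a JSON
#' sidecar so placements can be audited or overlaid on the image.
#'
#' @param rois a list of [roi_spec()] objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
roi_set_json <- function(rois, path) {
  payload <- lapply(rois, function(r) {
    list(label = r$label,
         center_voxel = r$center_voxel,
         semi_axes_mm = r$semi_axes_mm,
         slice_span = r$slice_span,
         shape = r$shape)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
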