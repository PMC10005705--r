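#' Calibrate a voxel volume to hydroxyapatite density
#'
#' Fits the ordinary least-squares line through (mean attenuation, known
#' density) across the calibration inserts and maps the whole volume through
#' it. Negative mapped densities are clipped to zero and counted.
#'
#' @param volume A raw-attenuation [voxel_volume()].
#' @param readings Data frame with columns `density` (mgHA/cm^3) and
#'   `mean_attenuation` (a.u.), one row per insert; at least two distinct
#'   densities and distinct attenuations.
#' @return A list with `curve` (a `calibration_curve`: slope, intercept,
#'   `r_squared`, the phantom table) and `volume` (the calibrated
#'   [voxel_volume()] with `n_clipped` attached as an attribute).
#' @examples
#' ph <- generate_phantom_volume(phantom_spec(length = 0.2, voxel_spacing = 0.02))
#' cal <- calibrate(ph$volume, ph$readings)
#' cal$curve
#' @export
calibrate <- function(volume, readings) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (isTRUE(volume$calibrated)) abort("volume is already calibrated.")
  readings <- as_tibble(readings)
  if (!all(c("density", "mean_attenuation") %in% names(readings))) {
    abort("`readings` needs columns `density` and `mean_attenuation`.")
  }
  if (length(unique(readings$density)) < 2L) {
    abort("at least two distinct phantom densities are required.")
  }
  if (diff(range(readings$mean_attenuation)) == 0) {
    abort("phantom attenuations are identical; calibration fit is degenerate.")
  }
  fit <- lm(density ~ mean_attenuation, data = readings)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (slope <= 0) warn("calibration slope is non-positive; check phantom readings.")
  mapped <- intercept + slope * volume$values
  n_clipped <- sum(mapped < 0)
  mapped[mapped < 0] <- 0
  curve <- structure(list(slope = slope, intercept = intercept,
                          r_squared = suppressWarnings(summary(fit)$r.squared),
                          table = readings),
                     class = "calibration_curve")
  out_vol <- voxel_volume(mapped, volume$spacing, calibrated = TRUE)
  attr(out_vol, "n_clipped") <- n_clipped
  list(curve = curve, volume = out_vol)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> density = %.4g + %.4g * attenuation (R^2 = %.6f)\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Map attenuation values through a calibration curve
#'
#' @param curve A `calibration_curve` from [calibrate()].
#' @param attenuation Attenuation values, a.u. (vectorised).
#' @return Densities, mgHA/cm^3 (not clipped).
#' @export
apply_calibration <- function(curve, attenuation) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$intercept + curve$slope * attenuation
}

#' Threshold segmentation of a calibrated volume
#'
#' @param volume A calibrated [voxel_volume()].
#' @param threshold Segmentation threshold, mgHA/cm^3, non-negative.
#'   Default 400.
#' @return A logical array (same dimensions) with attribute
#'   `masked_fraction`.
#' @export
segment_bone <- function(volume, threshold = 400) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (!isTRUE(volume$calibrated)) abort("`segment_bone()` expects a calibrated volume.")
  stop_if_not_number(threshold, "threshold", 0)
  mask <- volume$values >= threshold
  attr(mask, "masked_fraction") <- mean(mask)
  mask
}

#' Regional bone morphometry by axial block and transverse sector
#'
#' Splits the volume of interest into `n_blocks` equal axial blocks
#' (proximal block 1 to distal block `n_blocks`) and each transverse plane
#' into sectors about the per-slice section centroid: in `"half"` mode the
#' anterior/posterior halves along the AP axis and the medial/lateral halves
#' along the ML axis (each pair partitions the block), in `"quadrant"` mode
#' the four AP x ML quadrants. Per region it reports BV/TV (bone voxels over
#' VOI voxels), BMC (summed mineral mass, g) and BMD (BMC over bone volume,
#' g/cm^3; `NA` where the block holds no bone).
#'
#' The VOI spans the axial range from the growth-plate reference plane over
#' `voi_fraction` of the remaining length; with `growth_plate_z = NULL` the
#' whole volume is used.
#'
#' @param volume A calibrated [voxel_volume()].
#' @param mask Logical bone mask congruent with `volume` (from
#'   [segment_bone()]).
#' @param n_blocks Number of axial blocks, default 7.
#' @param sector_mode `"half"` (default) or `"quadrant"`.
#' @param growth_plate_z Axial world coordinate (mm) of the growth-plate
#'   plane, or `NULL` for the full volume.
#' @param voi_fraction Fraction of the axial length below the growth plate
#'   included in the VOI, default 0.8.
#' @return A tibble with one row per (block, sector) - sector `"all"` plus
#'   the sector halves or quadrants - and columns `block`, `sector`,
#'   `voi_voxels`, `bone_voxels`, `bvtv`, `bmc_g`, `bmd_g_cm3`.
#' @export
regional_morphometry <- function(volume, mask, n_blocks = 7L,
                                 sector_mode = c("half", "quadrant"),
                                 growth_plate_z = NULL, voi_fraction = 0.8) {
  stopifnot(inherits(volume, "voxel_volume"))
  sector_mode <- match.arg(sector_mode)
  if (!identical(dim(volume$values), dim(mask))) {
    abort("`mask` and `volume` must have identical dimensions.")
  }
  h <- volume$spacing
  nz <- dim(mask)[1]
  z_lo <- 1L
  z_hi <- nz
  if (!is.null(growth_plate_z)) {
    stop_if_not_number(growth_plate_z, "growth_plate_z", 0)
    stop_if_not_number(voi_fraction, "voi_fraction", 0, strict = TRUE)
    z_lo <- max(1L, 1L + floor(growth_plate_z / h))
    z_hi <- min(nz, z_lo + ceiling(voi_fraction * (nz - z_lo + 1L)) - 1L)
  }
  zs <- z_lo:z_hi
  block <- block_index(length(zs), n_blocks)
  voxel_mm3 <- h^3
  rows <- list()
  for (b in seq_len(n_blocks)) {
    zb <- zs[block == b]
    sub_mask <- mask[zb, , , drop = FALSE]
    sub_vals <- volume$values[zb, , , drop = FALSE]
    # per-slice sector labels about each section centroid
    sector_of <- function(v_mask) {
      lab_ap <- array(NA_character_, dim = dim(v_mask))
      lab_ml <- array(NA_character_, dim = dim(v_mask))
      for (k in seq_len(dim(v_mask)[1])) {
        sl <- v_mask[k, , ]
        if (!any(sl)) next
        idx <- which(sl, arr.ind = TRUE)
        c_ap <- mean(idx[, 1])
        c_ml <- mean(idx[, 2])
        ap_grid <- matrix(seq_len(nrow(sl)), nrow(sl), ncol(sl))
        ml_grid <- matrix(seq_len(ncol(sl)), nrow(sl), ncol(sl), byrow = TRUE)
        lab_ap[k, , ] <- ifelse(ap_grid <= c_ap, "anterior", "posterior")
        lab_ml[k, , ] <- ifelse(ml_grid <= c_ml, "medial", "lateral")
      }
      list(ap = lab_ap, ml = lab_ml)
    }
    labs <- sector_of(sub_mask)
    region_row <- function(sector, sel) {
      voi_n <- sum(sel)
      bone <- sub_mask & sel
      bone_n <- sum(bone)
      bmc <- sum(sub_vals[bone]) * voxel_mm3 * 1e-6
      tibble(block = b, sector = sector,
             voi_voxels = voi_n, bone_voxels = bone_n,
             bvtv = if (voi_n > 0) bone_n / voi_n else NA_real_,
             bmc_g = bmc,
             bmd_g_cm3 = if (bone_n > 0) bmc / (bone_n * voxel_mm3 * 1e-3) else NA_real_)
    }
    all_sel <- array(TRUE, dim = dim(sub_mask))
    rows[[length(rows) + 1L]] <- region_row("all", all_sel)
    if (sector_mode == "half") {
      for (s in c("anterior", "posterior")) {
        rows[[length(rows) + 1L]] <- region_row(s, !is.na(labs$ap) & labs$ap == s)
      }
      for (s in c("medial", "lateral")) {
        rows[[length(rows) + 1L]] <- region_row(s, !is.na(labs$ml) & labs$ml == s)
      }
    } else {
      for (sa in c("anterior", "posterior")) for (sm in c("medial", "lateral")) {
        sel <- !is.na(labs$ap) & labs$ap == sa & labs$ml == sm
        rows[[length(rows) + 1L]] <- region_row(paste(sa, sm, sep = "-"), sel)
      }
    }
  }
  bind_rows(rows)
}

#' Whole-bone summary of a regional morphometry table
#'
#' Summarises the per-block `"all"` rows the way a whole-bone mineral table
#' is reported: mean and range of block BMD, summed BMC, mean and range of
#' block BV/TV.
#'
#' @param morpho Output of [regional_morphometry()].
#' @return A one-row tibble.
#' @export
whole_bone_summary <- function(morpho) {
  blocks <- dplyr::filter(morpho, .data$sector == "all")
  tibble(
    bmd_mean_g_cm3 = mean(blocks$bmd_g_cm3, na.rm = TRUE),
    bmd_min_g_cm3 = suppressWarnings(min(blocks$bmd_g_cm3, na.rm = TRUE)),
    bmd_max_g_cm3 = suppressWarnings(max(blocks$bmd_g_cm3, na.rm = TRUE)),
    bmc_sum_g = sum(blocks$bmc_g),
    bvtv_mean = mean(blocks$bvtv, na.rm = TRUE),
    bvtv_min = suppressWarnings(min(blocks$bvtv, na.rm = TRUE)),
    bvtv_max = suppressWarnings(max(blocks$bvtv, na.rm = TRUE))
  )
}

#' Inner and outer diameters from cross-sectional mask slices
#'
#' For each requested axial slice, the periosteal (outer) area is the
#' hole-filled section and the medullary area is the filled section minus
#' bone; equivalent-circle diameters are \eqn{d = 2\sqrt{A/\pi}}. Solid
#' sections (no cavity) report `di = 0` and are flagged.
#'
#' @param mask Logical bone mask array (axial, AP, ML).
#' @param axial_positions Axial slice indices (1-based).
#' @param spacing Voxel spacing, mm.
#' @return A tibble with `axial_index`, `do_mm`, `di_mm`, `annular`.
#' @export
estimate_diameters <- function(mask, axial_positions, spacing) {
  stop_if_not_number(spacing, "spacing", 0, strict = TRUE)
  purrr::map_dfr(axial_positions, function(k) {
    if (k < 1L || k > dim(mask)[1]) abort("axial position outside the volume.")
    sl <- mask[k, , ]
    if (!any(sl)) abort(sprintf("axial slice %d does not intersect the mask.", k))
    filled <- EBImage::fillHull(matrix(as.integer(sl), nrow(sl), ncol(sl))) > 0
    a_outer <- sum(filled) * spacing^2
    a_med <- (sum(filled) - sum(sl)) * spacing^2
    tibble(axial_index = as.integer(k),
           do_mm = 2 * sqrt(a_outer / pi),
           di_mm = 2 * sqrt(max(a_med, 0) / pi),
           annular = a_med > 0)
  })
}

#' Percent area above threshold within rectangular ROIs
#'
#' Histomorphometry-style 2D area fraction: the mean over regions of
#' interest of the percentage of pixels at or above the threshold.
#'
#' @param image 2D numeric matrix.
#' @param rois Data frame with columns `row1`, `row2`, `col1`, `col2`
#'   (inclusive 1-based bounds), one row per ROI.
#' @param threshold Intensity threshold.
#' @return A list with `percent` (mean over ROIs) and `per_roi` (tibble).
#' @export
area_fraction <- function(image, rois, threshold) {
  if (!is.matrix(image)) abort("`image` must be a matrix.")
  rois <- as_tibble(rois)
  need <- c("row1", "row2", "col1", "col2")
  if (!all(need %in% names(rois)) || nrow(rois) == 0L) {
    abort("`rois` needs at least one row with columns row1, row2, col1, col2.")
  }
  per <- purrr::pmap_dfr(rois, function(row1, row2, col1, col2, ...) {
    if (row1 < 1 || col1 < 1 || row2 > nrow(image) || col2 > ncol(image) ||
        row2 < row1 || col2 < col1) {
      abort("ROI outside image bounds or empty.")
    }
    block <- image[row1:row2, col1:col2, drop = FALSE]
    tibble(n_pixels = length(block),
           percent = 100 * mean(block >= threshold))
  })
  list(percent = mean(per$percent), per_roi = per)
}
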