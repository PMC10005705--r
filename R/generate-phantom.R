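#' Specification of a synthetic hollow-tube voxel phantom
#'
#' Describes an idealized long-bone diaphysis for micro-CT emulation: a tube
#' whose outer and inner radii (and mineral density) may vary along the
#' axis, imaged on an isotropic voxel grid through an affine
#' attenuation-density map, together with hydroxyapatite calibration inserts
#' of known density. Scanner physics beyond the affine map plus Gaussian
#' noise is deliberately not modeled.
#'
#' @param outer_radius Outer radius, mm: a constant or a function of axial
#'   position z (mm).
#' @param inner_radius Inner radius, mm: constant or function of z; must stay
#'   strictly below the outer radius.
#' @param density Bone mineral density, mgHA/cm^3: constant or function of z.
#' @param length Axial length, mm.
#' @param voxel_spacing Isotropic voxel spacing, mm. Default 0.01 (10 um).
#' @param calibration_densities Insert densities, mgHA/cm^3; must include 0.
#' @param attenuation_slope,attenuation_intercept Affine map from density to
#'   scanner attenuation (arbitrary units): `a = intercept + slope * density`.
#' @param noise_sd Gaussian attenuation noise (a.u.), default 0.
#' @param max_voxels Desk-scale guard on the total voxel count.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(outer_radius = 0.685, inner_radius = 0.45,
                         density = 800, length = 3.5,
                         voxel_spacing = 0.01,
                         calibration_densities = c(0, 50, 200, 800, 1200),
                         attenuation_slope = 1, attenuation_intercept = 0,
                         noise_sd = 0, max_voxels = 5e7) {
  as_fun <- function(x, name) {
    if (is.function(x)) return(x)
    stop_if_not_number(x, name, 0)
    function(z) rep_len(x, length(z))
  }
  ro <- as_fun(outer_radius, "outer_radius")
  ri <- as_fun(inner_radius, "inner_radius")
  dens <- as_fun(density, "density")
  stop_if_not_number(length, "length", 0, strict = TRUE)
  stop_if_not_number(voxel_spacing, "voxel_spacing", 0, strict = TRUE)
  stop_if_not_number(attenuation_slope, "attenuation_slope", 0, strict = TRUE)
  stop_if_not_number(noise_sd, "noise_sd", 0)
  if (!any(calibration_densities == 0)) {
    abort("`calibration_densities` must include 0 (the background insert).")
  }
  zs <- seq(0, length, length.out = 64)
  if (any(ri(zs) >= ro(zs))) {
    abort("`inner_radius` must stay strictly below `outer_radius` along the axis.")
  }
  structure(list(outer_radius = ro, inner_radius = ri, density = dens,
                 length = length, voxel_spacing = voxel_spacing,
                 calibration_densities = sort(calibration_densities),
                 attenuation_slope = attenuation_slope,
                 attenuation_intercept = attenuation_intercept,
                 noise_sd = noise_sd, max_voxels = max_voxels),
            class = "phantom_spec")
}

#' In-memory voxel volume
#'
#' A minimal container for desk-scale micro-CT volumes: a 3D array with
#' axis order (axial, AP, ML), an isotropic voxel spacing in mm, and a flag
#' recording whether voxel values are raw attenuation (a.u.) or calibrated
#' density (mgHA/cm^3).
#'
#' @param values 3D numeric array, axes (axial, AP, ML).
#' @param spacing Voxel spacing, mm (isotropic).
#' @param calibrated Logical: values are mgHA/cm^3 (TRUE) or attenuation.
#' @return A `voxel_volume` object.
#' @export
voxel_volume <- function(values, spacing, calibrated = FALSE) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3D array (axial, AP, ML).")
  }
  stop_if_not_number(spacing, "spacing", 0, strict = TRUE)
  structure(list(values = values, spacing = spacing, calibrated = calibrated),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels @ %.4g mm, %s\n",
              d[1], d[2], d[3], x$spacing,
              if (x$calibrated) "mgHA/cm^3" else "attenuation (a.u.)"))
  invisible(x)
}

#' Generate a synthetic micro-CT phantom volume with calibration inserts
#'
#' Rasterizes the tube onto the voxel grid (voxel-center membership), maps
#' density through the affine attenuation model, adds noise, and synthesizes
#' one small homogeneous sub-volume per calibration density - separate
#' labeled inserts, mirroring scanner practice where phantoms sit beside the
#' specimen. Analytic per-block ground truth (bone volume, BV/TV, BMC, BMD)
#' is computed from the radius profiles, not from the voxelization.
#'
#' @param spec A [phantom_spec()].
#' @param seed Optional integer seed (noise only).
#' @param n_blocks Number of equal axial blocks for the analytic ground
#'   truth, default 7.
#' @return A list of class `phantom_volume`: `volume` (raw attenuation
#'   [voxel_volume()]), `truth_mask` (logical array of true bone voxels),
#'   `inserts` (named list of small attenuation arrays, one per calibration
#'   density), `readings` (tibble `density`, `mean_attenuation`), and
#'   `truth` (tibble of analytic per-block `bvtv`, `bmc_g`, `bmd_g_cm3`).
#' @export
generate_phantom_volume <- function(spec, seed = NULL, n_blocks = 7L) {
  stopifnot(inherits(spec, "phantom_spec"))
  local_seed_if(seed)
  h <- spec$voxel_spacing
  nz <- max(1L, round(spec$length / h))
  zc <- (seq_len(nz) - 0.5) * h
  ro <- spec$outer_radius(zc)
  ri <- spec$inner_radius(zc)
  dens <- spec$density(zc)
  # transverse extent is fixed in mm (snapped to 0.04 mm) so that BV/TV
  # denominators are comparable across voxel spacings
  zf <- seq(0, spec$length, length.out = 256)
  half <- ceiling((max(spec$outer_radius(zf)) + 0.02) / 0.04) * 0.04
  nxy <- 2L * max(1L, round(half / h))
  if (as.double(nz) * nxy * nxy > spec$max_voxels) {
    abort(sprintf("volume would need %.2g voxels, above the %.2g budget.",
                  as.double(nz) * nxy * nxy, spec$max_voxels))
  }
  xy <- (seq_len(nxy) - (nxy + 1) / 2) * h # voxel centers about the axis
  r2 <- outer(xy^2, xy^2, `+`)
  vals <- array(0, dim = c(nz, nxy, nxy))
  mask <- array(FALSE, dim = c(nz, nxy, nxy))
  for (k in seq_len(nz)) {
    bone <- r2 <= ro[k]^2 & r2 > ri[k]^2
    mask[k, , ] <- bone
    vals[k, , ] <- spec$attenuation_intercept +
      spec$attenuation_slope * dens[k] * bone
  }
  if (spec$noise_sd > 0) {
    vals <- vals + array(rnorm(length(vals), sd = spec$noise_sd), dim = dim(vals))
  }
  # calibration inserts: separate homogeneous sub-volumes
  insert_dim <- c(8L, 8L, 8L)
  inserts <- lapply(spec$calibration_densities, function(d) {
    a <- array(spec$attenuation_intercept + spec$attenuation_slope * d,
               dim = insert_dim)
    if (spec$noise_sd > 0) a <- a + array(rnorm(length(a), sd = spec$noise_sd),
                                          dim = insert_dim)
    a
  })
  names(inserts) <- paste0("d", spec$calibration_densities)
  readings <- tibble(
    density = spec$calibration_densities,
    mean_attenuation = unname(vapply(inserts, mean, numeric(1)))
  )
  # analytic truth: exact annulus areas per slice, midpoint rule along z
  block <- block_index(nz, n_blocks)
  a_grid <- (nxy * h)^2
  truth <- tibble(block = block, area_mm2 = pi * (ro^2 - ri^2), density = dens) %>%
    group_by(.data$block) %>%
    summarise(
      bvtv = sum(.data$area_mm2) / (a_grid * dplyr::n()),
      bmc_g = sum(.data$density * .data$area_mm2 * h) * 1e-6,
      bmd_g_cm3 = sum(.data$density * .data$area_mm2) /
        sum(.data$area_mm2) / 1000,
      .groups = "drop"
    )
  structure(list(volume = voxel_volume(vals, h, calibrated = FALSE),
                 truth_mask = mask, inserts = inserts, readings = readings,
                 truth = truth, spec = spec),
            class = "phantom_volume")
}

# near-equal partition of nz slices into n_blocks contiguous blocks
block_index <- function(nz, n_blocks) {
  as.integer(cut(seq_len(nz), breaks = n_blocks, labels = FALSE))
}

#' Rasterize an annulus onto a pixel grid
#'
#' Pixel-center membership test for a circular tube cross-section; the
#' voxel-integration oracle used to cross-check the closed-form area and
#' second-moment formulas.
#'
#' @param outer_radius,inner_radius Radii, mm (`inner_radius` may be 0).
#' @param spacing Pixel spacing, mm.
#' @return A logical matrix; attribute `spacing` carries the pixel size.
#' @export
rasterize_annulus <- function(outer_radius, inner_radius, spacing = 0.01) {
  stop_if_not_number(outer_radius, "outer_radius", 0, strict = TRUE)
  stop_if_not_number(inner_radius, "inner_radius", 0)
  if (inner_radius >= outer_radius) abort("`inner_radius` must be below `outer_radius`.")
  n <- 2L * ceiling((outer_radius + 2 * spacing) / spacing)
  xy <- (seq_len(n) - (n + 1) / 2) * spacing
  r2 <- outer(xy^2, xy^2, `+`)
  m <- r2 <= outer_radius^2 & r2 > inner_radius^2
  attr(m, "spacing") <- spacing
  m
}

#' Pixel-summed area and second moment of a rasterized section
#'
#' Numerical integration over a binary section mask: area = pixel count x
#' pixel area; second moment of area = sum of squared distances to the
#' centroidal bending axis x pixel area.
#'
#' @param mask Logical matrix (e.g. from [rasterize_annulus()]).
#' @param spacing Pixel spacing, mm; defaults to the mask's `spacing`
#'   attribute.
#' @return A list with `area_mm2` and `moment_mm4`.
#' @export
raster_section_properties <- function(mask, spacing = attr(mask, "spacing")) {
  stop_if_not_number(spacing, "spacing", 0, strict = TRUE)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list(area_mm2 = 0, moment_mm4 = 0))
  y <- idx[, 1] * spacing
  y <- y - mean(y) # centroidal axis
  list(area_mm2 = nrow(idx) * spacing^2,
       moment_mm4 = sum(y^2) * spacing^2)
}
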