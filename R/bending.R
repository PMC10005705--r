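#' Idealized circular tube cross-section of a long-bone midshaft
#'
#' Rodent tibial midshafts tested in three-point bending are conventionally
#' idealized as hollow circular tubes. All downstream beam formulas (stress,
#' modulus, second moment of area) act on this geometry.
#'
#' @param outer_radius Outer (periosteal) radius co, mm.
#' @param inner_radius Inner (medullary) radius ci, mm; `0 <= ci < co`.
#' @param span Support span L of the bending fixture, mm (default 6 mm).
#' @param tibial_length Whole-bone length, mm (optional; used for body-size
#'   normalization bookkeeping).
#'
#' @return A `tube_geometry` object.
#' @examples
#' tube_geometry(outer_radius = 0.685, inner_radius = 0.45)
#' @export
tube_geometry <- function(outer_radius, inner_radius, span = 6,
                          tibial_length = NA_real_) {
  stop_if_not_number(outer_radius, "outer_radius", 0, strict = TRUE)
  stop_if_not_number(inner_radius, "inner_radius", 0)
  stop_if_not_number(span, "span", 0, strict = TRUE)
  if (inner_radius >= outer_radius) {
    abort("`inner_radius` must be strictly less than `outer_radius`.")
  }
  structure(list(outer_radius = outer_radius, inner_radius = inner_radius,
                 span = span, tibial_length = tibial_length),
            class = "tube_geometry")
}

#' Second moment of area of a circular tube
#'
#' \eqn{I = \frac{\pi}{4}(c_o^4 - c_i^4)} in mm^4, the cross-sectional
#' geometric resistance to bending.
#'
#' @param geometry A [tube_geometry()].
#' @return Moment of inertia, mm^4.
#' @examples
#' moment_of_inertia(tube_geometry(0.685, 0.45)) # ~0.14 mm^4
#' @export
moment_of_inertia <- function(geometry) {
  stopifnot(inherits(geometry, "tube_geometry"))
  pi / 4 * (geometry$outer_radius^4 - geometry$inner_radius^4)
}

#' Cross-sectional area of a circular tube
#'
#' Annulus area \eqn{A = \pi(c_o^2 - c_i^2) = \frac{\pi}{4}(d_o^2 - d_i^2)}
#' in mm^2.
#'
#' @inheritParams moment_of_inertia
#' @return Area, mm^2.
#' @examples
#' cross_sectional_area(tube_geometry(0.685, 0.45)) # ~0.84 mm^2
#' @export
cross_sectional_area <- function(geometry) {
  stopifnot(inherits(geometry, "tube_geometry"))
  pi * (geometry$outer_radius^2 - geometry$inner_radius^2)
}

#' Outer-fibre bending stress under three-point load
#'
#' \eqn{\sigma = F L c_o / (4 I)}: with F in N and lengths in mm this is
#' N/mm^2, i.e. MPa, directly.
#'
#' @param load Applied load F, N (vectorised, non-negative).
#' @inheritParams moment_of_inertia
#' @return Stress, MPa.
#' @export
stress_at <- function(load, geometry) {
  stopifnot(inherits(geometry, "tube_geometry"))
  if (any(load < 0)) abort("`load` must be non-negative.")
  load * geometry$span * geometry$outer_radius / (4 * moment_of_inertia(geometry))
}

#' Elastic modulus from the linear-region stiffness
#'
#' \eqn{E = S L^3 / (48 I)} for a centrally loaded beam on two supports,
#' where S = F/d is the load-displacement slope. With S in N/mm and lengths
#' in mm the result is MPa; it is returned in GPa.
#'
#' @param slope Linear-region stiffness S, N/mm, positive.
#' @inheritParams moment_of_inertia
#' @return Elastic modulus, GPa.
#' @examples
#' elastic_modulus(60, tube_geometry(0.8, 0.4, span = 6))
#' @export
elastic_modulus <- function(slope, geometry) {
  stopifnot(inherits(geometry, "tube_geometry"))
  stop_if_not_number(slope, "slope", 0, strict = TRUE)
  slope * geometry$span^3 / (48 * moment_of_inertia(geometry)) / 1000
}

#' Inner radius from inner-to-outer diameter ratios
#'
#' Cross-sections imaged at several axial positions give pairs of inner and
#' outer diameters; the mean of the per-section ratios di/do, applied to a
#' caliper-measured outer radius, estimates the inner radius of specimens
#' that were not imaged. The mean of ratios (not the ratio of means) is used.
#'
#' @param outer_radius Caliper outer radius, mm.
#' @param ratio_samples A data frame with columns `di` and `do` (mm), one row
#'   per imaged cross-section, all `di < do`.
#' @return Estimated inner radius, mm.
#' @examples
#' inner_radius_from_ratio(0.685, data.frame(di = 0.90, do = 1.37))
#' @export
inner_radius_from_ratio <- function(outer_radius, ratio_samples) {
  stop_if_not_number(outer_radius, "outer_radius", 0, strict = TRUE)
  ratio_samples <- as.data.frame(ratio_samples)
  if (nrow(ratio_samples) < 1L) abort("`ratio_samples` must contain at least one pair.")
  if (!all(c("di", "do") %in% names(ratio_samples))) {
    abort("`ratio_samples` needs columns `di` and `do`.")
  }
  if (any(ratio_samples$di >= ratio_samples$do)) {
    abort("every `di` must be smaller than its `do`.")
  }
  outer_radius * mean(ratio_samples$di / ratio_samples$do)
}

# ---- curve analysis ---------------------------------------------------------

as_curve <- function(curve) {
  curve <- as_tibble(curve)
  if (!all(c("displacement_mm", "load_n") %in% names(curve))) {
    abort("a load-displacement curve needs columns `displacement_mm` and `load_n`.")
  }
  if (nrow(curve) < 10L) abort("a load-displacement curve needs at least 10 samples.")
  if (any(diff(curve$displacement_mm) <= 0)) {
    abort("`displacement_mm` must be strictly increasing.")
  }
  curve
}

#' Least-squares slope of the initial linear region
#'
#' Selects the elastic region of a load-displacement curve and fits a
#' straight line through it. The default window is the 20-80% segment of the
#' rise to half-maximum load, which excludes both toe-in at contact and the
#' post-yield region; the downstream quantity is the stiffness S = F/d that
#' feeds [elastic_modulus()] and the offset construction in [find_yield()].
#'
#' @param curve Tibble with `displacement_mm`, `load_n`.
#' @param fit_window Either a fraction in (0, 1] interpreted as the leading
#'   fraction of the rise to half-maximum load, or `NULL` for the default
#'   20-80% segment of that rise.
#' @return A list with `slope` (N/mm), `intercept` (N), `r_squared`, and the
#'   index `window` used.
#' @export
linear_slope <- function(curve, fit_window = NULL) {
  curve <- as_curve(curve)
  half_idx <- which(curve$load_n >= max(curve$load_n) / 2)[1]
  if (is.na(half_idx) || half_idx < 3L) abort("curve rises too fast to delimit a linear region.")
  d_half <- curve$displacement_mm[half_idx]
  if (is.null(fit_window)) {
    lo <- 0.2 * d_half
    hi <- 0.8 * d_half
  } else {
    stop_if_not_number(fit_window, "fit_window", 0, strict = TRUE)
    if (fit_window > 1) abort("`fit_window` must be in (0, 1].")
    lo <- 0
    hi <- fit_window * d_half
  }
  idx <- which(curve$displacement_mm >= lo & curve$displacement_mm <= hi)
  if (length(idx) < 3L) abort("fewer than 3 samples in the linear-fit window.")
  fit <- lm(load_n ~ displacement_mm, data = curve[idx, ])
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared), window = range(idx))
}

#' Offset yield point of a load-displacement curve
#'
#' Constructs a line parallel to the elastic slope, offset along the
#' displacement axis (default 0.015 mm), and returns its first intersection
#' with the curve, linearly interpolated between samples. A curve that never
#' crosses the offset line (e.g. purely linear to failure) yields `NULL`
#' components and `detected = FALSE`.
#'
#' @param curve Tibble with `displacement_mm`, `load_n`.
#' @param slope Elastic slope S, N/mm (from [linear_slope()]).
#' @param offset Displacement offset, mm, positive. Default 0.015 mm.
#' @return A list with `displacement_mm`, `load_n`, `detected`.
#' @export
find_yield <- function(curve, slope, offset = 0.015) {
  curve <- as_curve(curve)
  stop_if_not_number(slope, "slope", 0, strict = TRUE)
  stop_if_not_number(offset, "offset", 0)
  d <- curve$displacement_mm
  f <- curve$load_n
  # residual of the curve above the offset line; yield = first strict downward
  # crossing (a zero-offset line coincides with the elastic segment, so the
  # crossing interpolates back to the kink where the residual was still 0)
  g <- f - slope * (d - offset)
  below <- which(g < 0 & d > offset)
  if (length(below) == 0L) {
    return(list(displacement_mm = NA_real_, load_n = NA_real_, detected = FALSE))
  }
  j <- below[1]
  if (j == 1L) {
    return(list(displacement_mm = d[j], load_n = f[j], detected = TRUE))
  }
  i <- j - 1L
  w <- g[i] / (g[i] - g[j]) # linear interpolation of the crossing
  list(displacement_mm = d[i] + w * (d[j] - d[i]),
       load_n = f[i] + w * (f[j] - f[i]),
       detected = TRUE)
}

#' Ultimate point, fracture point and post-yield displacement
#'
#' Ultimate = global load maximum. Fracture = last sample before the terminal
#' drop below `fracture_fraction` of the ultimate load (a curve with no such
#' drop ends at its last sample and is flagged). PYD = displacement from
#' yield to fracture, a ductility measure.
#'
#' @param curve Tibble with `displacement_mm`, `load_n`.
#' @param yield A yield point list from [find_yield()] (optional; without it
#'   PYD is `NA`).
#' @param fracture_fraction Terminal-drop threshold as a fraction of ultimate
#'   load, default 0.1.
#' @return A list with `ultimate`, `fracture` (each `displacement_mm`,
#'   `load_n`), `pyd_mm`, and `fracture_detected`.
#' @export
key_points <- function(curve, yield = NULL, fracture_fraction = 0.1) {
  curve <- as_curve(curve)
  stop_if_not_number(fracture_fraction, "fracture_fraction", 0, strict = TRUE)
  d <- curve$displacement_mm
  f <- curve$load_n
  iu <- which.max(f)
  post <- which(f < fracture_fraction * f[iu])
  post <- post[post > iu]
  if (length(post) == 0L) {
    ifr <- length(f)
    detected <- FALSE
  } else {
    ifr <- post[1] - 1L
    detected <- TRUE
  }
  pyd <- if (!is.null(yield) && isTRUE(yield$detected)) {
    max(d[ifr] - yield$displacement_mm, 0)
  } else NA_real_
  list(ultimate = list(displacement_mm = d[iu], load_n = f[iu]),
       fracture = list(displacement_mm = d[ifr], load_n = f[ifr]),
       pyd_mm = pyd, fracture_detected = detected)
}

#' Detect pop-in events (sudden load drops)
#'
#' Pop-ins are transient load drops during bending attributed to microcrack
#' initiation or propagation. An event is a decrease of more than
#' `drop_fraction` of the current load between successive samples; the
#' terminal fracture drop (to below `fracture_fraction` of ultimate) is
#' excluded.
#'
#' @param curve Tibble with `displacement_mm`, `load_n`.
#' @param drop_fraction Relative drop threshold in (0, 1), default 0.05.
#' @param fracture_fraction Terminal-drop exclusion threshold, default 0.1.
#' @return A tibble with one row per event: `displacement_mm`, `load_before_n`,
#'   `load_after_n`, `drop_n`, `drop_fraction`.
#' @export
detect_popins <- function(curve, drop_fraction = 0.05, fracture_fraction = 0.1) {
  curve <- as_curve(curve)
  if (drop_fraction <= 0 || drop_fraction >= 1) abort("`drop_fraction` must be in (0, 1).")
  d <- curve$displacement_mm
  f <- curve$load_n
  ult <- max(f)
  i <- seq_len(length(f) - 1L)
  drop <- f[i] - f[i + 1L]
  is_event <- drop > drop_fraction * f[i] & f[i + 1L] >= fracture_fraction * ult
  idx <- which(is_event)
  tibble(displacement_mm = d[idx + 1L],
         load_before_n = f[idx],
         load_after_n = f[idx + 1L],
         drop_n = drop[idx],
         drop_fraction = drop[idx] / f[idx])
}

#' Full three-point-bending analysis of one curve
#'
#' Chains [linear_slope()], [find_yield()], [key_points()] and
#' [detect_popins()], converts the key loads to outer-fibre stresses via
#' [stress_at()] and the stiffness to a modulus via [elastic_modulus()].
#'
#' @param curve Tibble with `displacement_mm`, `load_n`.
#' @param geometry A [tube_geometry()].
#' @param offset Yield offset, mm.
#' @param fit_window Passed to [linear_slope()].
#' @param drop_fraction Passed to [detect_popins()].
#' @param fracture_fraction Passed to [key_points()].
#' @return An object of class `bending_result`: a list holding the stresses
#'   (MPa), modulus (GPa), PYD (mm), geometry-derived area and moment of
#'   inertia, pop-in table, and fit diagnostics. Use [tidy()] for a one-row
#'   tibble.
#' @examples
#' truth <- bending_ground_truth(E_true = 4, geometry = tube_geometry(0.7, 0.4),
#'                               yield_load = 12, hardening_slope = 5,
#'                               fracture_displacement = 0.6)
#' curve <- generate_bending_curve(truth)
#' analyze_bending(curve, truth$geometry)
#' @export
analyze_bending <- function(curve, geometry, offset = 0.015, fit_window = NULL,
                            drop_fraction = 0.05, fracture_fraction = 0.1) {
  curve <- as_curve(curve)
  stopifnot(inherits(geometry, "tube_geometry"))
  fit <- linear_slope(curve, fit_window)
  yld <- find_yield(curve, fit$slope, offset)
  kp <- key_points(curve, yld, fracture_fraction)
  pops <- detect_popins(curve, drop_fraction, fracture_fraction)
  res <- list(
    yield_stress_mpa = if (yld$detected) stress_at(yld$load_n, geometry) else NA_real_,
    ultimate_stress_mpa = stress_at(kp$ultimate$load_n, geometry),
    fracture_stress_mpa = stress_at(kp$fracture$load_n, geometry),
    elastic_modulus_gpa = elastic_modulus(fit$slope, geometry),
    pyd_mm = kp$pyd_mm,
    area_mm2 = cross_sectional_area(geometry),
    moment_of_inertia_mm4 = moment_of_inertia(geometry),
    yield = yld, ultimate = kp$ultimate, fracture = kp$fracture,
    popins = pops,
    slope_n_mm = fit$slope, fit_r_squared = fit$r_squared,
    fracture_detected = kp$fracture_detected,
    normalized = FALSE, normalization_factor = NA_real_,
    geometry = geometry
  )
  structure(res, class = "bending_result")
}

#' @export
print.bending_result <- function(x, ...) {
  cat("<bending_result>\n")
  cat(sprintf("  E = %.3f GPa, sigma_y = %.1f, sigma_u = %.1f, sigma_f = %.1f MPa\n",
              x$elastic_modulus_gpa, x$yield_stress_mpa, x$ultimate_stress_mpa,
              x$fracture_stress_mpa))
  cat(sprintf("  PYD = %.3f mm, pop-ins: %d, normalized: %s\n",
              x$pyd_mm, nrow(x$popins), x$normalized))
  invisible(x)
}

#' Body-size normalization of strength parameters
#'
#' Divides the four strength/stiffness outputs (yield, ultimate and fracture
#' stress, elastic modulus) by the ratio of body weight (g) to tibial length
#' (mm), the conventional adjustment when group body masses diverge. The
#' factor is recorded so normalization is exactly invertible; normalizing an
#' already-normalized result is an error.
#'
#' @param result A `bending_result`.
#' @param body_weight Body weight, g.
#' @param tibial_length Tibial length, mm.
#' @return The normalized `bending_result`.
#' @export
normalize_by_body_size <- function(result, body_weight, tibial_length) {
  stopifnot(inherits(result, "bending_result"))
  stop_if_not_number(body_weight, "body_weight", 0, strict = TRUE)
  stop_if_not_number(tibial_length, "tibial_length", 0, strict = TRUE)
  if (isTRUE(result$normalized)) abort("result is already body-size normalized.")
  factor <- body_weight / tibial_length
  for (fld in c("yield_stress_mpa", "ultimate_stress_mpa",
                "fracture_stress_mpa", "elastic_modulus_gpa")) {
    result[[fld]] <- result[[fld]] / factor
  }
  result$normalized <- TRUE
  result$normalization_factor <- factor
  result
}
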