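#' Tidy a bending analysis result
#'
#' @param x A `bending_result` from [analyze_bending()].
#' @param ... Unused.
#' @return A one-row tibble of the scalar mechanical outputs.
#' @export
tidy.bending_result <- function(x, ...) {
  tibble(
    yield_stress_mpa = x$yield_stress_mpa,
    ultimate_stress_mpa = x$ultimate_stress_mpa,
    fracture_stress_mpa = x$fracture_stress_mpa,
    elastic_modulus_gpa = x$elastic_modulus_gpa,
    pyd_mm = x$pyd_mm,
    area_mm2 = x$area_mm2,
    moment_of_inertia_mm4 = x$moment_of_inertia_mm4,
    n_popins = nrow(x$popins),
    slope_n_mm = x$slope_n_mm,
    fit_r_squared = x$fit_r_squared,
    normalized = x$normalized,
    normalization_factor = x$normalization_factor
  )
}

#' @rdname tidy.bending_result
#' @export
glance.bending_result <- function(x, ...) {
  tibble(fit_r_squared = x$fit_r_squared,
         fracture_detected = x$fracture_detected,
         n_popins = nrow(x$popins),
         normalized = x$normalized)
}

#' Tidy a calibration curve
#'
#' @param x A `calibration_curve` from [calibrate()].
#' @param ... Unused.
#' @return The phantom table with fitted densities and residuals.
#' @export
tidy.calibration_curve <- function(x, ...) {
  mutate(x$table,
         fitted_density = x$intercept + x$slope * .data$mean_attenuation,
         residual = .data$density - .data$fitted_density)
}

#' @rdname tidy.calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         n_phantoms = nrow(x$table))
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` from [mann_whitney_exact()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(U = x$U, n1 = x$n1, n2 = x$n2, p_two_sided = x$p_two_sided,
         method = x$method, ties = x$ties)
}
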