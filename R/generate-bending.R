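#' Ground truth for a synthetic three-point-bending test
#'
#' Describes an elastoplastic specimen: a linear elastic segment of stiffness
#' \eqn{S = 48 E I / L^3}, a bilinear hardening branch past a planted yield
#' load, optional instantaneous pop-in load drops, and a terminal fracture
#' drop to zero. Units follow the bending module: E in GPa, geometry in mm,
#' loads in N.
#'
#' @param E_true True elastic modulus, GPa.
#' @param geometry A [tube_geometry()].
#' @param yield_load Load at the elastic/plastic kink, N.
#' @param hardening_slope Post-yield slope, N/mm (non-negative; may be 0).
#' @param fracture_displacement Displacement at fracture, mm; must exceed the
#'   yield displacement `yield_load / S`.
#' @param popin_events Data frame with columns `displacement_mm` and
#'   `drop_fraction` (each in (0, 1)); may have zero rows.
#' @return A `bending_ground_truth` object; `$slope_n_mm` holds the elastic
#'   stiffness implied by `E_true` and the geometry.
#' @export
bending_ground_truth <- function(E_true, geometry, yield_load, hardening_slope,
                                 fracture_displacement,
                                 popin_events = NULL) {
  stopifnot(inherits(geometry, "tube_geometry"))
  stop_if_not_number(E_true, "E_true", 0, strict = TRUE)
  stop_if_not_number(yield_load, "yield_load", 0, strict = TRUE)
  stop_if_not_number(hardening_slope, "hardening_slope", 0)
  stop_if_not_number(fracture_displacement, "fracture_displacement", 0, strict = TRUE)
  # E GPa = kN/mm^2, so S = 48 * (1000 E) * I / L^3 is N/mm
  slope <- 48 * (E_true * 1000) * moment_of_inertia(geometry) / geometry$span^3
  d_yield <- yield_load / slope
  if (fracture_displacement <= d_yield) {
    abort("`fracture_displacement` must exceed the yield displacement.")
  }
  if (is.null(popin_events)) {
    popin_events <- tibble(displacement_mm = numeric(), drop_fraction = numeric())
  }
  popin_events <- as_tibble(popin_events)
  if (nrow(popin_events) > 0) {
    if (any(popin_events$drop_fraction <= 0 | popin_events$drop_fraction >= 1)) {
      abort("pop-in `drop_fraction`s must lie in (0, 1).")
    }
  }
  structure(list(E_true = E_true, geometry = geometry, yield_load = yield_load,
                 hardening_slope = hardening_slope,
                 fracture_displacement = fracture_displacement,
                 popin_events = popin_events,
                 slope_n_mm = slope, yield_displacement_mm = d_yield),
            class = "bending_ground_truth")
}

#' Generate a synthetic load-displacement curve
#'
#' Samples the piecewise-linear elastoplastic response on a uniform
#' displacement grid. Pop-ins are instantaneous vertical drops: at each
#' planted displacement the load loses the stated fraction of its current
#' value and the curve resumes with the same slope. The record ends one
#' sample past `fracture_displacement` with the load dropped to zero, so the
#' terminal fracture drop is part of the curve.
#'
#' @param truth A [bending_ground_truth()].
#' @param sampling_step Displacement step, mm, default 0.002.
#' @param noise_sd Gaussian load noise, N (additive; negative loads clipped
#'   to zero). Default 0.
#' @param seed Optional integer seed.
#' @return A tibble with `displacement_mm`, `load_n` and attribute `truth`.
#' @export
generate_bending_curve <- function(truth, sampling_step = 0.002, noise_sd = 0,
                                   seed = NULL) {
  stopifnot(inherits(truth, "bending_ground_truth"))
  stop_if_not_number(sampling_step, "sampling_step", 0, strict = TRUE)
  stop_if_not_number(noise_sd, "noise_sd", 0)
  local_seed_if(seed)
  d <- seq(0, truth$fracture_displacement, by = sampling_step)
  if (abs(tail(d, 1) - truth$fracture_displacement) > 1e-12) {
    d <- c(d, truth$fracture_displacement)
  }
  S <- truth$slope_n_mm
  dy <- truth$yield_displacement_mm
  f <- ifelse(d <= dy, S * d,
              truth$yield_load + truth$hardening_slope * (d - dy))
  if (nrow(truth$popin_events) > 0) {
    ev <- dplyr::arrange(truth$popin_events, .data$displacement_mm)
    for (k in seq_len(nrow(ev))) {
      after <- d >= ev$displacement_mm[k]
      if (!any(after)) next
      j <- which(after)[1]
      f[after] <- f[after] - ev$drop_fraction[k] * f[j]
    }
  }
  if (noise_sd > 0) f <- pmax(f + rnorm(length(f), sd = noise_sd), 0)
  # terminal drop to zero one sample past fracture
  d <- c(d, tail(d, 1) + sampling_step)
  f <- c(f, 0)
  out <- new_curve_tbl(d, pmax(f, 0))
  attr(out, "truth") <- truth
  out
}
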