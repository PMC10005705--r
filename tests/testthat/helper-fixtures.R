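# shared builders for small, fully specified fixtures

ovx_geometry <- function() tube_geometry(0.685, 0.45, span = 6, tibial_length = 21.30)
control_geometry <- function() tube_geometry(0.73, 0.43, span = 6, tibial_length = 18.82)

# elastoplastic truth with study-scale modulus and ductility
make_truth <- function(E_true = 4.63, geometry = ovx_geometry(),
                       yield_load = 14, hardening_slope = 6, pyd = 0.47,
                       popins = NULL) {
  S <- 48 * E_true * 1000 * moment_of_inertia(geometry) / geometry$span^3
  bending_ground_truth(E_true, geometry, yield_load, hardening_slope,
                       fracture_displacement = yield_load / S + pyd,
                       popin_events = popins)
}

# where the 0.015 mm offset line meets the hardening branch of a bilinear
# curve (the geometric-construction oracle for offset yield detection)
offset_yield_expectation <- function(truth, offset = 0.015) {
  S <- truth$slope_n_mm
  h <- truth$hardening_slope
  d <- truth$yield_displacement_mm + S * offset / (S - h)
  list(displacement_mm = d, load_n = S * (d - offset))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
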