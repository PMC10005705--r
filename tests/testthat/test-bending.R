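test_that("tube section formulas reproduce caliper-scale reference values", {
  # mean diameters of the study groups force these moments and areas
  expect_equal(round(moment_of_inertia(ovx_geometry()), 2), 0.14)
  expect_equal(round(moment_of_inertia(control_geometry()), 2), 0.20)
  expect_equal(round(cross_sectional_area(ovx_geometry()), 2), 0.84)
  expect_equal(moment_of_inertia(tube_geometry(1, 0)), pi / 4, tolerance = 1e-12)
  expect_equal(cross_sectional_area(tube_geometry(1, 1 - 1e-12)), 0,
               tolerance = 1e-9)
  # raster-integration oracle agrees with both closed forms
  for (geom in list(ovx_geometry(), control_geometry(),
                    tube_geometry(0.695, 0.36))) {
    props <- raster_section_properties(
      rasterize_annulus(geom$outer_radius, geom$inner_radius, 0.01))
    expect_rel_equal(props$area_mm2, cross_sectional_area(geom), 0.02)
    expect_rel_equal(props$moment_mm4, moment_of_inertia(geom), 0.02)
  }
})

test_that("stress and modulus conversions match hand-computed cases", {
  g <- ovx_geometry()
  # hand oracle: F L co / (4 I) for F = 10 N, frozen before implementation
  expect_equal(stress_at(10, g), 73.01914, tolerance = 1e-5)
  expect_equal(stress_at(0, g), 0)
  # linearity in co at fixed I (construct geometry with same I)
  expect_equal(stress_at(10, g) * 2,
               10 * g$span * (2 * g$outer_radius) / (4 * moment_of_inertia(g)))
  # hand oracle: S L^3 / (48 I) for S = 60 N/mm, L = 6 mm, I = 0.2 mm^4
  g2 <- tube_geometry((0.2 * 4 / pi)^0.25, 0, span = 6) # I = 0.2 exactly
  expect_equal(moment_of_inertia(g2), 0.2, tolerance = 1e-12)
  expect_equal(elastic_modulus(60, g2), 1.35, tolerance = 1e-9)
  # halving I at fixed slope doubles E
  g3 <- tube_geometry((0.1 * 4 / pi)^0.25, 0, span = 6)
  expect_equal(elastic_modulus(60, g3), 2.7, tolerance = 1e-9)
})

test_that("linear slope recovers planted stiffness on clean and noisy curves", {
  d <- seq(0.001, 1, by = 0.001)
  line <- tibble::tibble(displacement_mm = d, load_n = 50 * d)
  expect_equal(linear_slope(line)$slope, 50, tolerance = 1e-9)
  tt <- make_truth()
  cu <- generate_bending_curve(tt)
  expect_rel_equal(linear_slope(cu)$slope, tt$slope_n_mm, 1e-3)
  # noisy slope lands within 3 SE of the plant in >= 95% of seeds
  hits <- vapply(1:200, function(s) {
    cun <- generate_bending_curve(tt, noise_sd = 0.3, seed = s)
    fit <- linear_slope(cun)
    idx <- fit$window
    sub <- cun[idx[1]:idx[2], ]
    se <- suppressWarnings(summary(lm(load_n ~ displacement_mm, sub)))$coefficients[2, 2]
    abs(fit$slope - tt$slope_n_mm) <= 3 * se
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  expect_error(linear_slope(line, fit_window = 2), "in \\(0, 1\\]")
})

test_that("offset yield detection matches the geometric construction", {
  tt <- make_truth()
  cu <- generate_bending_curve(tt)
  fit <- linear_slope(cu)
  yld <- find_yield(cu, fit$slope, offset = 0.015)
  exp_y <- offset_yield_expectation(tt, 0.015)
  expect_true(yld$detected)
  expect_lt(abs(yld$displacement_mm - exp_y$displacement_mm), 0.002) # 1 step
  expect_lt(abs(yld$load_n - exp_y$load_n), 0.05)
  # zero offset returns the planted kink exactly
  y0 <- find_yield(cu, tt$slope_n_mm, offset = 0)
  expect_lt(abs(y0$displacement_mm - tt$yield_displacement_mm), 0.002) # 1 step
  # a purely linear curve never meets the parallel offset line
  d <- seq(0.001, 1, by = 0.01)
  line <- tibble::tibble(displacement_mm = d, load_n = 50 * d)
  expect_false(find_yield(line, 50, offset = 0.015)$detected)
})

test_that("key points and PYD recover planted ductility", {
  tt <- make_truth(pyd = 0.47)
  cu <- generate_bending_curve(tt)
  res <- analyze_bending(cu, tt$geometry)
  exp_y <- offset_yield_expectation(tt, 0.015)
  expect_equal(res$fracture$displacement_mm, tt$fracture_displacement,
               tolerance = 0.004) # 2 sampling steps
  expect_equal(res$pyd_mm, tt$fracture_displacement - exp_y$displacement_mm,
               tolerance = 0.004)
  expect_gte(res$ultimate_stress_mpa, res$yield_stress_mpa)
  expect_gte(res$ultimate_stress_mpa, res$fracture_stress_mpa)
  # curve ending at its maximum: ultimate and fracture coincide, flagged
  d <- seq(0.001, 0.5, by = 0.001)
  mono <- tibble::tibble(displacement_mm = d, load_n = 30 * d)
  kp <- key_points(mono)
  expect_false(kp$fracture_detected)
  expect_equal(kp$ultimate$load_n, kp$fracture$load_n)
  # sub-threshold pop-ins do not shift the ultimate point
  tt2 <- make_truth(popins = data.frame(displacement_mm = 0.25, drop_fraction = 0.08))
  kp2 <- key_points(generate_bending_curve(tt2))
  kp1 <- key_points(generate_bending_curve(make_truth()))
  expect_equal(kp2$ultimate$displacement_mm, kp1$ultimate$displacement_mm,
               tolerance = 1e-9)
})

test_that("pop-in detection is threshold-monotone and skips the fracture drop", {
  d <- seq(0.001, 0.5, by = 0.001)
  mono <- tibble::tibble(displacement_mm = d, load_n = 30 * d)
  expect_equal(nrow(detect_popins(mono)), 0)
  tt <- make_truth(popins = data.frame(displacement_mm = c(0.25, 0.35),
                                       drop_fraction = c(0.1, 0.1)))
  cu <- generate_bending_curve(tt)
  ev <- detect_popins(cu, drop_fraction = 0.05)
  expect_equal(nrow(ev), 2)
  expect_equal(nrow(detect_popins(cu, drop_fraction = 0.5)), 0)
})

test_that("round-trip recovery holds across a grid of plants", {
  grid <- expand.grid(E_true = c(2.85, 3.5, 4.63),
                      pyd = c(0.28, 0.47),
                      geom = 1:2)
  geoms <- list(ovx_geometry(), control_geometry())
  for (i in seq_len(nrow(grid))) {
    tt <- make_truth(E_true = grid$E_true[i], geometry = geoms[[grid$geom[i]]],
                     pyd = grid$pyd[i])
    res <- analyze_bending(generate_bending_curve(tt), tt$geometry)
    expect_rel_equal(res$elastic_modulus_gpa, tt$E_true, 0.01)
    exp_y <- offset_yield_expectation(tt, 0.015)
    expect_lt(abs(res$yield$displacement_mm - exp_y$displacement_mm), 0.002)
    expect_lt(abs(res$pyd_mm - (tt$fracture_displacement - exp_y$displacement_mm)),
              0.004)
  }
})

test_that("body-size normalization divides strengths and inverts exactly", {
  tt <- make_truth()
  res <- analyze_bending(generate_bending_curve(tt), tt$geometry)
  # identity factor leaves results unchanged
  same <- normalize_by_body_size(res, body_weight = 20, tibial_length = 20)
  expect_equal(same$ultimate_stress_mpa, res$ultimate_stress_mpa)
  # factor 2 halves all stresses
  half <- normalize_by_body_size(res, body_weight = 40, tibial_length = 20)
  expect_equal(half$ultimate_stress_mpa, res$ultimate_stress_mpa / 2)
  expect_equal(half$elastic_modulus_gpa, res$elastic_modulus_gpa / 2)
  # two animals with identical raw strength and weights w1, w2: normalized
  # ratio is w2/w1 (endpoint means of the heaviest and lightest groups)
  n1 <- normalize_by_body_size(res, 45.09, 20)
  n2 <- normalize_by_body_size(res, 28.05, 20)
  expect_equal(n1$ultimate_stress_mpa / n2$ultimate_stress_mpa, 28.05 / 45.09,
               tolerance = 1e-12)
  # invertible to near machine precision, and double application rejected
  expect_equal(half$ultimate_stress_mpa * half$normalization_factor,
               res$ultimate_stress_mpa, tolerance = 1e-12)
  expect_error(normalize_by_body_size(half, 40, 20), "already")
})

test_that("inner radius uses the mean of diameter ratios", {
  expect_equal(inner_radius_from_ratio(0.7, data.frame(di = c(1, 2), do = c(2, 4))),
               0.35)
  expect_equal(inner_radius_from_ratio(0.685, data.frame(di = 0.90, do = 1.37)),
               0.45, tolerance = 1e-9)
  # mean of ratios differs from ratio of means on heterogeneous sections:
  # counterexample constructed ahead of the implementation
  pairs <- data.frame(di = c(0.2, 0.9), do = c(0.4, 1.0))
  expect_equal(inner_radius_from_ratio(1, pairs), 0.7)
  expect_false(isTRUE(all.equal(mean(pairs$di) / mean(pairs$do), 0.7)))
  expect_error(inner_radius_from_ratio(1, data.frame(di = numeric(), do = numeric())),
               "at least one")
})
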