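test_that("SLS closed-form moduli match hand-computed values and limits", {
  p <- sls_params(E_inst = 3, E_eq = 1, tau = 1)
  # f = 0.1 Hz: E' = 1 + 2 (0.2 pi)^2 / (1 + (0.2 pi)^2), frozen from the
  # closed form evaluated by hand
  m <- sls_moduli(p, 0.1)
  expect_equal(m$storage_mpa, 1.5660864, tolerance = 1e-6)
  # loss modulus maximum (E_inst - E_eq)/2 at omega * tau = 1
  f_star <- 1 / (2 * pi)
  expect_equal(sls_moduli(p, f_star)$loss_mpa, 1, tolerance = 1e-12)
  grid <- sls_moduli(p, 10^seq(-3, 3, by = 0.1))
  expect_lte(max(grid$loss_mpa), 1 + 1e-12)
  # elastic high-frequency limit: strain amplitude -> sigma_a / E_inst, lag -> 0
  hi <- sls_moduli(p, 1e6)
  expect_equal(hi$storage_mpa, 3, tolerance = 1e-6)
  expect_equal(hi$tan_delta, 0, tolerance = 1e-5)
  lo <- sls_moduli(p, 1e-7)
  expect_equal(lo$storage_mpa, 1, tolerance = 1e-6)
})

test_that("noise-free DMA traces carry the exact steady-state response", {
  p <- sls_params(2.8, 1.4, 0.7)
  proto <- dma_protocol()
  tr <- generate_dma_trace(p, proto, 1)
  # stress is exactly the programmed sinusoid
  expect_equal(tr$stress_mpa,
               proto$stress_mean + proto$stress_amplitude * sin(2 * pi * tr$time_s),
               tolerance = 1e-12)
  # numerically estimated phase lag equals atan(E''/E') of the truth
  truth <- attr(tr, "truth")
  fs <- fit_sinusoid(tr$stress_mpa, tr$time_s, 1)
  fe <- fit_sinusoid(tr$strain, tr$time_s, 1)
  expect_equal(fs$phase - fe$phase, atan(truth$loss_mpa / truth$storage_mpa),
               tolerance = 1e-6)
  # strain amplitude = sigma_a / |E*|
  expect_equal(fe$amplitude,
               proto$stress_amplitude / sqrt(truth$storage_mpa^2 + truth$loss_mpa^2),
               tolerance = 1e-9)
  expect_error(generate_dma_trace(p, proto, 0.3), "not part of")
})

test_that("generators are deterministic under a fixed seed", {
  p <- sls_params(3, 1, 1, noise_sd = 0.01)
  expect_identical(generate_dma_trace(p, dma_protocol(), 10, seed = 42),
                   generate_dma_trace(p, dma_protocol(), 10, seed = 42))
  tt <- make_truth()
  expect_identical(generate_bending_curve(tt, noise_sd = 0.1, seed = 42),
                   generate_bending_curve(tt, noise_sd = 0.1, seed = 42))
  sp <- cohort_spec()
  expect_identical(generate_cohort(sp, seed = 42), generate_cohort(sp, seed = 42))
  ps <- phantom_spec(length = 0.1, voxel_spacing = 0.02, noise_sd = 5)
  expect_identical(generate_phantom_volume(ps, seed = 42)$volume$values,
                   generate_phantom_volume(ps, seed = 42)$volume$values)
})

test_that("bending curves have the planted elastic slope and stay physical", {
  tt <- make_truth()
  cu <- generate_bending_curve(tt)
  # slope of the initial elastic segment is exactly 48 E I / L^3
  fit <- lm(load_n ~ displacement_mm,
            data = dplyr::filter(cu, displacement_mm < 0.8 * tt$yield_displacement_mm))
  expect_equal(unname(coef(fit)[2]), tt$slope_n_mm, tolerance = 1e-9)
  expect_true(all(diff(cu$displacement_mm) > 0))
  expect_true(all(cu$load_n >= 0))
  # planted pop-ins drop the load by their fraction at the planted spot
  tt2 <- make_truth(popins = data.frame(displacement_mm = c(0.25, 0.35),
                                        drop_fraction = c(0.1, 0.1)))
  cu2 <- generate_bending_curve(tt2)
  ev <- detect_popins(cu2, drop_fraction = 0.05)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$displacement_mm, c(0.25, 0.35), tolerance = 0.002 + 1e-9)
  expect_error(tube_geometry(0.4, 0.5), "strictly less")
})

test_that("phantom ground truth agrees with voxel integration", {
  # BMC: analytic truth vs voxel-summed mass within 2% at default-scale spacing
  ps <- phantom_spec(outer_radius = 0.685, inner_radius = 0.45, density = 800,
                     length = 0.35, voxel_spacing = 0.01)
  ph <- generate_phantom_volume(ps)
  h <- ph$volume$spacing
  vox_bmc <- sapply(split(seq_len(dim(ph$truth_mask)[1]),
                          osteomech:::block_index(dim(ph$truth_mask)[1], 7)),
                    function(zs) sum(ph$volume$values[zs, , ][ph$truth_mask[zs, , ]]) * h^3 * 1e-6)
  expect_true(all(abs(unname(vox_bmc) - ph$truth$bmc_g) / ph$truth$bmc_g < 0.02))
  # solid cylinder: interior BV/TV ground truth uses the full annulus area
  solid <- generate_phantom_volume(phantom_spec(outer_radius = 0.4,
                                                inner_radius = 0,
                                                density = 600, length = 0.1,
                                                voxel_spacing = 0.02))
  expect_true(all(abs(solid$truth$bmd_g_cm3 - 0.6) < 1e-12))
  # voxel-summed second moment of the tube vs closed form within 2%
  m <- rasterize_annulus(0.685, 0.45, spacing = 0.01)
  props <- raster_section_properties(m)
  expect_rel_equal(props$moment_mm4, pi / 4 * (0.685^4 - 0.45^4), 0.02)
  expect_rel_equal(props$area_mm2, pi * (0.685^2 - 0.45^2), 0.02)
  # desk-scale voxel budget guard
  expect_error(generate_phantom_volume(phantom_spec(length = 50,
                                                    voxel_spacing = 0.001)),
               "budget")
})

test_that("noise-free cohorts are exactly linear with zero within-group SE", {
  coh <- generate_cohort(cohort_spec(weekly_noise_sd = 0))
  cs <- cohort_summary(coh)
  # planted endpoint means: every animal's gain equals final - start
  expect_equal(cs$gain_mean_g[cs$group == "control"], 9.13, tolerance = 1e-9)
  expect_equal(cs$gain_mean_g[cs$group == "OVX+E2"], 6.36, tolerance = 1e-9)
  expect_equal(cs$start_se_g, rep(0, 3), tolerance = 1e-12)
  # linear trajectory: second differences vanish
  one <- dplyr::filter(coh, animal_id == "control_01")
  expect_equal(diff(diff(one$body_weight_g)), rep(0, 10), tolerance = 1e-12)
  # lean + fat never exceeds body weight even with noise
  noisy <- generate_cohort(cohort_spec(weekly_noise_sd = 3), seed = 11)
  expect_true(all(noisy$lean_g + noisy$fat_g <= noisy$body_weight_g + 1e-9))
})

test_that("planted group separation is recovered as complete separation", {
  coh <- generate_cohort(cohort_spec(weekly_noise_sd = 1), seed = 3)
  wk12 <- dplyr::filter(coh, week == 12)
  cmp <- mann_whitney_exact(wk12$body_weight_g[wk12$group == "control"],
                            wk12$body_weight_g[wk12$group == "OVX"])
  # planted effect (28 vs 45 g) dwarfs 1 g noise: U = 0, exact floor p
  expect_equal(cmp$U, 0)
  expect_equal(cmp$p_two_sided, 2 / 924, tolerance = 1e-12)
})

test_that("diet omega fractions are mass-weighted with honest intervals", {
  single <- diet_omega_fractions(data.frame(mass_g = 100, omega3 = 0.13,
                                            omega6 = 0.55, omega9 = 0.18))
  expect_equal(single$percent, c(13, 55, 18))
  # soybean + lard blend: the omega-9 interval brackets the labeled 44.2%
  blend <- diet_omega_fractions(data.frame(
    mass_g = c(25, 245),
    omega3 = c(0.13, 0),
    omega6_min = c(0.55, 0.06), omega6_max = c(0.55, 0.10),
    omega9_min = c(0.18, 0.44), omega9_max = c(0.18, 0.47)
  ))
  o9 <- blend[blend$omega == "omega9", ]
  expect_equal(o9$percent_min, 41.59259, tolerance = 1e-5)
  expect_equal(o9$percent_max, 44.31481, tolerance = 1e-5)
  expect_true(o9$percent_min <= 44.2 && 44.2 <= o9$percent_max)
  expect_lte(sum(blend$percent), 100)
  expect_error(diet_omega_fractions(data.frame()), "at least one")
})
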