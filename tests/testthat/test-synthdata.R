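test_that("head phantom paints exact tissue levels into -1000 background", {
  gs <- c(16, 32, 32); sp <- c(3, 3, 3)
  ext <- (gs - 1) * sp; ctr <- ext / 2
  spec <- phantom_spec(gs, sp, list(
    phantom_component("body", ctr, ext * 0.35, 0)))
  ph <- generate_head_phantom(spec)
  body <- phantom_body_mask(ph)$values
  expect_true(all(ph$values[body] == 0))
  expect_true(all(ph$values[!body] == -1000))

  spec2 <- phantom_spec(gs, sp, list(
    phantom_component("body", ctr, ext * 0.40, 30),
    phantom_component("bone", ctr, ext * 0.25, 700)))
  ph2 <- generate_head_phantom(spec2)
  expect_identical(sort(unique(as.numeric(ph2$values))), c(-1000, 30, 700))
})

test_that("phantom generation is bit-reproducible under a fixed seed", {
  s <- random_head_spec(42, grid_shape = c(12, 32, 32), texture_sd = 15)
  expect_identical(generate_head_phantom(s)$values,
                   generate_head_phantom(s)$values)
  s2 <- random_head_spec(42, grid_shape = c(12, 32, 32), texture_sd = 15)
  expect_identical(generate_head_phantom(s)$values,
                   generate_head_phantom(s2)$values)
})

test_that("partially overlapping components with different HU are rejected", {
  gs <- c(10, 24, 24); sp <- c(2, 2, 2)
  ext <- (gs - 1) * sp; ctr <- ext / 2
  spec <- phantom_spec(gs, sp, list(
    phantom_component("body", ctr, ext * 0.45, 30),
    phantom_component("blob_a", ctr - c(0, 4, 0), c(6, 8, 8), 100),
    phantom_component("blob_b", ctr + c(0, 4, 0), c(6, 8, 8), 300)))
  expect_error(generate_head_phantom(spec), "blob_a.*blob_b|contradictory")
  spec_out <- phantom_spec(gs, sp, list(
    phantom_component("body", ctr, c(4, 6, 6), 30),
    phantom_component("huge", ctr, ext * 0.45, 100)))
  expect_error(generate_head_phantom(spec_out), "not enclosed")
})

test_that("null degradation is the identity and a shift curve shifts exactly", {
  ph <- generate_head_phantom(phantom_spec(c(12, 32, 32)))
  m <- phantom_body_mask(ph)
  null_par <- degradation_params()
  expect_identical(degrade_to_cbct(ph, null_par, m)$values, ph$values)
  shift <- degradation_params(hu_curve = function(v) v + 100)
  out <- degrade_to_cbct(ph, shift, m)
  expect_equal(out$values, ph$values + 100, tolerance = 1e-12)
})

test_that("degradation noise is zero-mean at the CLT scale and seeded", {
  ph <- generate_head_phantom(phantom_spec(c(40, 96, 96)))
  m <- phantom_body_mask(ph)
  n_in <- sum(m$values)
  expect_gt(n_in, 1e5)
  par <- degradation_params(noise_sigma = 20, seed = 11L)
  out <- degrade_to_cbct(ph, par, m)
  d <- (out$values - ph$values)[m$values]
  expect_lt(abs(mean(d)), 3 * 20 / sqrt(n_in))
  out2 <- degrade_to_cbct(ph, par, m)
  expect_identical(out$values, out2$values)
})

test_that("non-monotone HU curves are rejected", {
  expect_error(degradation_params(hu_curve = function(v) -v),
               "strictly increasing")
  expect_error(piecewise_hu_curve(c(0, 100), c(50, 50)),
               "strictly increasing")
})

test_that("cupping lowers the body centre but not the periphery or outside", {
  ph <- generate_head_phantom(phantom_spec(c(12, 48, 48)))
  m <- phantom_body_mask(ph)
  par <- degradation_params(cupping_amplitude = 60)
  out <- degrade_to_cbct(ph, par, m)
  d <- ph$values - out$values
  expect_true(all(d[!m$values] == 0))
  s <- 6
  ctr_deficit <- d[s, 24, 24]
  expect_gt(ctr_deficit, 40)
  expect_lte(max(d), 60 + 1e-9)
})

test_that("calibration phantom readout matches nominal and affine-mapped HUs", {
  spec <- calibration_phantom_spec()
  r0 <- scan_calibration_phantom(spec, NULL)
  expect_equal(nrow(r0), 9)
  expect_equal(r0$relative_ed,
               c(1.00, 0.20, 0.50, 0.97, 0.99, 1.06, 1.07, 1.16, 1.61))
  expect_equal(r0$mean_hu, spec$insert_nominal_hus, tolerance = 1e-12)

  aff <- degradation_params(hu_curve = function(v) 0.8 * v - 50)
  r1 <- scan_calibration_phantom(spec, aff)
  expect_equal(r1$mean_hu, 0.8 * spec$insert_nominal_hus - 50,
               tolerance = 1e-12)

  # sorted by ED, readings must increase when nominal HUs increase with ED
  o <- order(r0$relative_ed)
  expect_true(all(diff(r0$mean_hu[o]) > 0))
  expect_true(all(diff(r1$mean_hu[o]) > 0))
})

test_that("scan through a degradation recovers the curve at insert HUs", {
  spec <- calibration_phantom_spec()
  par <- cohort_degradation(noise_sigma = 5, seed = 3L)
  r <- scan_calibration_phantom(spec, par)
  expected <- par$hu_curve(spec$insert_nominal_hus)
  # noise-of-mean bound: sigma / sqrt(roi voxels), generous 5x margin
  expect_true(all(abs(r$mean_hu - expected) < 5 * 5 / sqrt(10)))
})

test_that("dose grids are Gaussian-blob sums with exact construction limits", {
  sp <- c(3, 3, 3)
  ctr <- c(9, 9, 9) * 3  # voxel (9,9,9) centre in mm (0-based)
  single <- list(list(center_mm = ctr, width_mm = 10, peak_gy = 70))
  g <- generate_dose_grid(c(19, 19, 19), sp, single)
  expect_equal(max(g$values), 70)
  expect_equal(g$values[10, 10, 10], 70)
  empty <- generate_dose_grid(c(8, 8, 8), sp, list())
  expect_true(all(empty$values == 0))
  double <- generate_dose_grid(c(19, 19, 19), sp, c(single, single))
  expect_equal(double$values, 2 * g$values, tolerance = 1e-12)
  expect_error(generate_dose_grid(c(8, 8, 8), sp,
                                  list(list(center_mm = ctr, width_mm = 0,
                                            peak_gy = 1))), "width")
})
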