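test_that("resampling onto the same grid or a constant volume is exact", {
  v <- volume(array(stats::rnorm(6 * 8 * 8), c(6, 8, 8)), spacing = c(2, 1, 1))
  expect_identical(resample_to_grid(v, v)$values, v$values)

  cv <- const_volume(120, dims = c(8, 10, 10), spacing = c(1, 1, 1))
  ref <- volume(array(0, c(4, 5, 5)), spacing = c(2, 2, 2),
                origin = c(0.5, 0.5, 0.5))
  out <- resample_to_grid(cv, ref)
  expect_true(all(abs(out$values - 120) < 1e-9))
})

test_that("downsampling a linear ramp matches analytic interpolation", {
  n <- 33
  vals <- array(rep(seq(0, 32, length.out = n), times = 5 * 5), c(n, 5, 5))
  mov <- volume(vals, spacing = c(1, 4, 4))
  ref <- volume(array(0, c(16, 5, 5)), spacing = c(2, 4, 4),
                origin = c(0.5, 0, 0))
  out <- resample_to_grid(mov, ref)
  expected <- 0.5 + 2 * (0:15)
  expect_lt(max(abs(out$values[, 3, 3] - expected)), 1e-6)
})

test_that("body mask equals a clean cube and rejects all-air volumes", {
  cv <- cube_volume(c(12, 14, 14), inside = 0, margin = 4)
  m <- make_body_mask(cv, threshold_hu = -400)
  truth <- cube_mask(c(12, 14, 14), margin = 4)
  expect_identical(m$values, truth$values)
  expect_error(make_body_mask(const_volume(-1000), threshold_hu = -400),
               "empty mask")
})

test_that("body mask recovers the phantom body with cavities filled", {
  ph <- generate_head_phantom(phantom_spec(c(24, 64, 64)))
  truth <- phantom_body_mask(ph)$values
  m <- make_body_mask(ph)$values
  dice <- 2 * sum(m & truth) / (sum(m) + sum(truth))
  expect_gte(dice, 0.99)
})

test_that("clip_and_flatten enforces range and background, idempotently", {
  dims <- c(6, 8, 8)
  m <- cube_mask(dims, margin = 2)
  v <- volume(array(stats::rnorm(prod(dims), 300, 900), dims))
  v$values[4, 4, 4] <- 2500   # inside mask
  v$values[4, 5, 5] <- -1200  # inside mask
  v$values[1, 1, 1] <- 300    # outside mask
  out <- clip_and_flatten(v, m)
  expect_equal(out$values[4, 4, 4], 2000)
  expect_equal(out$values[4, 5, 5], -1000)
  expect_equal(out$values[1, 1, 1], -1000)
  expect_true(all(out$values >= -1000 & out$values <= 2000))
  expect_identical(clip_and_flatten(out, m)$values, out$values)
  expect_error(clip_and_flatten(v, cube_mask(c(5, 8, 8))), "mask grid")
})

test_that("normalization maps endpoints exactly and round-trips", {
  expect_equal(normalize_hu(-1000), -1)
  expect_equal(normalize_hu(2000), 1)
  expect_equal(normalize_hu(500), 0)
  v <- withr::with_seed(13, stats::runif(1000, -1000, 2000))
  expect_lt(max(abs(denormalize_hu(normalize_hu(v)) - v)), 1e-9)
  expect_error(normalize_hu(2500), "clip")
  expect_error(denormalize_hu(1.5), "outside")
})

test_that("center crop follows the high-side convention", {
  sl <- matrix(seq_len(410 * 410), 410, 410)
  cr <- center_crop(sl, 256)
  # 0-based window [77, 333) on both axes
  expect_identical(cr, sl[78:333, 78:333])
  expect_identical(center_crop(cr, 256), cr)
  expect_identical(center_crop(matrix(7, 300, 300), 256),
                   matrix(7, 256, 256))
  expect_error(center_crop(matrix(0, 100, 100), 256), "smaller")
  # odd leftover: extra row dropped from the high-index side
  odd <- matrix(seq_len(5 * 5), 5, 5)
  expect_identical(center_crop(odd, 4), odd[1:4, 1:4])
})

test_that("patient split reproduces the published bookkeeping and is seeded", {
  ids <- sprintf("pt%02d", 1:52)
  sp <- build_dataset(ids, split_seed = 99L)
  expect_equal(sp$counts$train_patients, 41)
  expect_equal(sp$counts$validation_patients, 11)
  expect_equal(sp$counts$train_slices, 10824)
  expect_equal(sp$counts$validation_slices, 2904)
  expect_length(intersect(sp$train, sp$validation), 0)
  sp2 <- build_dataset(ids, split_seed = 99L)
  expect_identical(sp$train, sp2$train)

  tiny <- build_dataset(c("a", "b"), split_seed = 1L, train_fraction = 0.5,
                        slices_per_patient = 10L)
  expect_equal(tiny$counts$train_patients, 1)
  expect_equal(tiny$counts$validation_patients, 1)
  expect_length(intersect(tiny$train, tiny$validation), 0)
})

test_that("patient-level disjointness holds across seeds", {
  ids <- letters[1:10]
  for (s in 1:20) {
    sp <- build_dataset(ids, split_seed = s, train_fraction = 0.7,
                        slices_per_patient = 4L)
    expect_length(intersect(sp$train, sp$validation), 0)
    expect_setequal(c(sp$train, sp$validation), ids)
  }
})

test_that("volumes round-trip through NIfTI with spacing intact", {
  v <- volume(array(stats::rnorm(4 * 6 * 6), c(4, 6, 6)),
              spacing = c(3, 1.5, 1.5), origin = c(1, 2, 3))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  r <- read_volume(f)
  expect_equal(r$values, v$values, tolerance = 1e-6)
  expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
})
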