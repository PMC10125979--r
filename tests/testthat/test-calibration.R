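test_that("curves reproduce their nodes and interpolate linearly", {
  eds <- c(1.00, 0.20, 0.50, 0.97, 0.99, 1.06, 1.07, 1.16, 1.61)
  hus <- default_insert_hus(eds)
  cu <- build_curve(data.frame(relative_ed = eds, mean_hu = hus))
  expect_equal(nrow(cu$points), 9)
  # nodes reproduced exactly, in sorted-HU order
  o <- order(hus)
  expect_equal(eval_curve(cu, hus[o]), eds[o], tolerance = 1e-12)

  two <- build_curve(data.frame(relative_ed = c(0, 1), mean_hu = c(-1000, 0)))
  expect_equal(eval_curve(two, -500), 0.5)
})

test_that("curve evaluation matches a brute-force segment-search oracle", {
  pts <- withr::with_seed(7, {
    hu <- sort(stats::runif(9, -900, 1500))
    ed <- cumsum(stats::runif(9, 0.01, 0.3))
    list(hu = hu, ed = ed)
  })
  cu <- build_curve(data.frame(relative_ed = pts$ed, mean_hu = pts$hu))
  qs <- withr::with_seed(8, stats::runif(100, -1000, 2000))
  oracle <- vapply(qs, function(q) {
    if (q <= pts$hu[1]) return(pts$ed[1])
    if (q >= pts$hu[9]) return(pts$ed[9])
    i <- max(which(pts$hu <= q))
    t <- (q - pts$hu[i]) / (pts$hu[i + 1] - pts$hu[i])
    pts$ed[i] + t * (pts$ed[i + 1] - pts$ed[i])
  }, numeric(1))
  expect_equal(eval_curve(cu, qs), oracle, tolerance = 1e-12)
})

test_that("curve construction rejects invalid readings", {
  expect_error(build_curve(data.frame(relative_ed = 1, mean_hu = 0)),
               "at least 2")
  expect_error(build_curve(data.frame(relative_ed = c(1, 2),
                                      mean_hu = c(5, 5))), "duplicate")
  expect_error(build_curve(data.frame(relative_ed = c(1.0, 0.5),
                                      mean_hu = c(0, 100))), "non-monotone")
})

test_that("composed correction is identity for equal curves and cancels shifts", {
  eds <- c(0.2, 0.5, 1.0, 1.2, 1.6)
  hus <- c(-800, -500, 0, 300, 950)
  ct <- build_curve(data.frame(relative_ed = eds, mean_hu = hus))
  map_id <- compose_correction(ct, ct)
  expect_equal(map_id$fun(hus), hus, tolerance = 1e-9)
  between <- seq(-800, 950, length.out = 50)
  expect_equal(map_id$fun(between), between, tolerance = 1e-9)

  cb <- build_curve(data.frame(relative_ed = eds, mean_hu = hus + 100))
  map_sh <- compose_correction(cb, ct)
  expect_equal(map_sh$fun(hus + 100), hus, tolerance = 1e-9)
})

test_that("composition matches a sequential interpolate-then-bisect oracle", {
  pts <- withr::with_seed(21, {
    list(hu_cb = sort(stats::runif(7, -900, 1200)),
         hu_ct = sort(stats::runif(7, -950, 1400)),
         ed = sort(stats::runif(7, 0.1, 1.8)))
  })
  cb <- build_curve(data.frame(relative_ed = pts$ed, mean_hu = pts$hu_cb))
  ct <- build_curve(data.frame(relative_ed = pts$ed, mean_hu = pts$hu_ct))
  map <- compose_correction(cb, ct, extrapolation_mode = "clamp")
  qs <- withr::with_seed(22, stats::runif(1000, -1000, 2000))
  ed_q <- eval_curve(cb, qs, "clamp")
  bisect_invert <- function(edv) {
    lo <- pts$hu_ct[1]; hi <- pts$hu_ct[7]
    if (edv <= pts$ed[1]) return(lo)
    if (edv >= pts$ed[7]) return(hi)
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (eval_curve(ct, mid) < edv) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  oracle <- vapply(ed_q, bisect_invert, numeric(1))
  expect_lt(max(abs(map$fun(qs) - oracle)), 1e-6)
})

test_that("correction map is monotone and errors on flat ED segments", {
  eds <- c(0.2, 0.5, 0.5, 1.0)
  hus <- c(-800, -400, -100, 0)
  flat <- build_curve(data.frame(relative_ed = eds, mean_hu = hus))
  ok <- build_curve(data.frame(relative_ed = c(0.2, 0.5, 1.0, 1.5),
                               mean_hu = c(-800, -400, 0, 800)))
  expect_error(compose_correction(ok, flat), "not invertible")

  map <- compose_correction(ok, ok)
  v <- sort(withr::with_seed(3, stats::runif(200, -1000, 2000)))
  expect_true(all(diff(map$fun(v)) >= -1e-9))
})

test_that("voxelwise correction respects masks and preserves the grid", {
  vol <- const_volume(150, spacing = c(2, 1, 1))
  eds <- c(0.2, 1.0, 1.6)
  ct <- build_curve(data.frame(relative_ed = eds, mean_hu = c(-800, 0, 950)))
  cb <- build_curve(data.frame(relative_ed = eds, mean_hu = c(-700, 100, 1050)))
  map <- compose_correction(cb, ct)  # subtracts 100 at nodes
  out <- apply_correction(vol, map)
  expect_equal(out$values, array(50, dim = dim(vol$values)), tolerance = 1e-9)
  expect_equal(out$spacing, vol$spacing)

  m <- cube_mask(dim(vol$values), margin = 2)
  out2 <- apply_correction(vol, map, m)
  expect_true(all(out2$values[!m$values] == 150))
  expect_equal(unique(as.numeric(out2$values[m$values])), 50, tolerance = 1e-9)
})

test_that("curve CSV and correction-map serialization round-trip", {
  eds <- c(0.2, 1.0, 1.6)
  cu <- build_curve(data.frame(relative_ed = eds, mean_hu = c(-780, 5, 930)))
  f <- tempfile(fileext = ".csv")
  write_curve_csv(cu, f)
  expect_equal(read_curve_csv(f)$points, cu$points)
  d <- tempfile()
  cb <- build_curve(data.frame(relative_ed = eds, mean_hu = c(-700, 60, 1010)))
  map <- compose_correction(cb, cu, extrapolation_mode = "linear")
  write_correction_map(map, d)
  map2 <- read_correction_map(d)
  expect_equal(map2$extrapolation_mode, "linear")
  v <- seq(-1000, 2000, by = 37)
  expect_equal(map2$fun(v), map$fun(v), tolerance = 1e-12)
})
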