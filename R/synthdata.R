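#' Digital head-phantom specification
#'
#' Describes a stack of ellipsoidal tissue components painted, in list order,
#' into a uniform air background (-1000 HU). The first component is the body
#' and must enclose every later component; later components override earlier
#' ones where they nest (skull inside body, brain inside skull, air cavities
#' inside brain). Partial overlap between two non-body components with
#' different HU is rejected as contradictory.
#'
#' @param grid_shape integer length-3 voxel counts, axis order
#'   (slice, row, column).
#' @param spacing_mm numeric length-3 voxel size in mm, all > 0.
#' @param tissue_components list of components from [phantom_component()];
#'   `NULL` uses the default head model of [default_head_components()].
#' @param texture_sd optional Gaussian HU texture inside the body (0 = off).
#' @param seed integer seed driving texture noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40, 64, 64), spacing_mm = c(3, 3, 3),
                         tissue_components = NULL, texture_sd = 0, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("`grid_shape` must be 3 voxel counts >= 4")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be positive on all axes")
  if (is.null(tissue_components))
    tissue_components <- default_head_components(grid_shape, spacing_mm)
  hus <- vapply(tissue_components, function(cc) cc$hu, numeric(1))
  if (any(hus < -1000 | hus > 2000))
    stop("component HU must lie within [-1000, 2000]")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 tissue_components = tissue_components,
                 texture_sd = texture_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param name component label used in error messages.
#' @param center_mm,radii_mm ellipsoid centre and semi-axes in mm
#'   (axis order slice, row, column).
#' @param hu nominal Hounsfield value of the component.
#' @export
phantom_component <- function(name, center_mm, radii_mm, hu) {
  stopifnot(length(center_mm) == 3L, length(radii_mm) == 3L,
            all(radii_mm > 0), is.finite(hu))
  list(name = name, center_mm = as.numeric(center_mm),
       radii_mm = as.numeric(radii_mm), hu = as.numeric(hu))
}

#' @rdname phantom_spec
#' @export
default_head_components <- function(grid_shape, spacing_mm) {
  ext <- (grid_shape - 1) * spacing_mm
  ctr <- ext / 2
  body_r <- c(0.46 * ext[1], 0.42 * ext[2], 0.38 * ext[3])
  skull_r <- body_r * c(0.88, 0.84, 0.84)
  brain_r <- skull_r * 0.86
  cav_r <- pmin(brain_r * 0.22, 12)
  list(
    phantom_component("body", ctr, body_r, 30),
    phantom_component("skull", ctr, skull_r, 700),
    phantom_component("brain", ctr, brain_r, 30),
    phantom_component("cavity_left",
                      ctr + c(-0.35 * brain_r[1], 0.35 * brain_r[2], -0.3 * brain_r[3]),
                      cav_r, -1000),
    phantom_component("cavity_right",
                      ctr + c(-0.35 * brain_r[1], 0.35 * brain_r[2], 0.3 * brain_r[3]),
                      cav_r, -1000),
    phantom_component("lesion",
                      ctr + c(0.3 * brain_r[1], -0.25 * brain_r[2], 0.2 * brain_r[3]),
                      pmin(brain_r * 0.18, 10), 80)
  )
}

#' Randomly varied head phantom for cohort simulations
#'
#' Jitters the default head geometry (component centres, semi-axes and soft
#' tissue/lesion HU) so that a cohort of phantoms shows inter-"patient"
#' anatomical variation while keeping the tissue classes fixed.
#'
#' @inheritParams phantom_spec
#' @param seed integer; drives the jitter, one phantom per seed.
#' @return A `phantom_spec`.
#' @export
random_head_spec <- function(seed, grid_shape = c(40, 64, 64),
                             spacing_mm = c(3, 3, 3), texture_sd = 0) {
  withr::with_seed(as.integer(seed), {
    comps <- default_head_components(grid_shape, spacing_mm)
    # one per-axis anatomy scale keeps the tissue shells concentric/nested
    scale <- stats::runif(3, 0.92, 1.05)
    for (i in seq_along(comps)) {
      comps[[i]]$radii_mm <- comps[[i]]$radii_mm * scale
      if (i > 3) {
        # cavities and lesions: small extra jitter, ample nesting margin
        comps[[i]]$center_mm <- comps[[i]]$center_mm +
          stats::runif(3, -1, 1) * spacing_mm
        comps[[i]]$radii_mm <- comps[[i]]$radii_mm * stats::runif(1, 0.85, 1.1)
      }
      if (comps[[i]]$hu > -1000 && comps[[i]]$hu < 600)
        comps[[i]]$hu <- comps[[i]]$hu + round(stats::runif(1, -10, 10))
    }
    phantom_spec(grid_shape, spacing_mm, comps, texture_sd = texture_sd,
                 seed = as.integer(seed))
  })
}

ellipsoid_mask <- function(grid_shape, spacing_mm, center_mm, radii_mm) {
  i <- (seq_len(grid_shape[1]) - 1) * spacing_mm[1]
  j <- (seq_len(grid_shape[2]) - 1) * spacing_mm[2]
  k <- (seq_len(grid_shape[3]) - 1) * spacing_mm[3]
  di <- ((i - center_mm[1]) / radii_mm[1])^2
  dj <- ((j - center_mm[2]) / radii_mm[2])^2
  dk <- ((k - center_mm[3]) / radii_mm[3])^2
  d <- outer(outer(di, dj, `+`), dk, `+`)
  d <= 1
}

#' Generate a head phantom CT volume
#'
#' Paints the components of a [phantom_spec()] into a -1000 HU background.
#' The returned volume carries the phantom's true body mask (body component,
#' cavities included) as attribute `"body_mask"`; see [phantom_body_mask()].
#'
#' @param spec a [phantom_spec()].
#' @return A `ct_volume` in HU, deterministic given `spec$seed`.
#' @export
generate_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape; sp <- spec$spacing_mm
  comps <- spec$tissue_components
  masks <- lapply(comps, function(cc)
    ellipsoid_mask(gs, sp, cc$center_mm, cc$radii_mm))
  if (length(comps) > 1) {
    body <- masks[[1]]
    for (i in seq_along(comps)[-1]) {
      if (any(masks[[i]] & !body))
        stop(sprintf("component '%s' is not enclosed by the body component '%s'",
                     comps[[i]]$name, comps[[1]]$name))
    }
    if (length(comps) > 2) {
      for (i in 2:(length(comps) - 1)) for (j in (i + 1):length(comps)) {
        ov <- masks[[i]] & masks[[j]]
        # partial overlap (neither nested in the other) with different HU
        if (any(ov) && comps[[i]]$hu != comps[[j]]$hu &&
            any(masks[[i]] & !masks[[j]]) && any(masks[[j]] & !masks[[i]]))
          stop(sprintf("components '%s' and '%s' overlap with contradictory HU",
                       comps[[i]]$name, comps[[j]]$name))
      }
    }
  }
  vals <- array(-1000, dim = gs)
  for (i in seq_along(comps)) vals[masks[[i]]] <- comps[[i]]$hu
  if (spec$texture_sd > 0) {
    withr::with_seed(spec$seed, {
      noise <- stats::rnorm(sum(masks[[1]]), 0, spec$texture_sd)
    })
    vals[masks[[1]]] <- pmin(pmax(vals[masks[[1]]] + noise, -1000), 2000)
  }
  vol <- volume(vals, spacing = sp)
  attr(vol, "body_mask") <- binary_mask(masks[[1]], spacing = sp)
  vol
}

#' @rdname generate_head_phantom
#' @param vol a phantom volume from `generate_head_phantom()`.
#' @export
phantom_body_mask <- function(vol) {
  m <- attr(vol, "body_mask")
  if (is.null(m)) stop("volume has no attached ground-truth body mask")
  m
}

#' CBCT degradation model
#'
#' Describes how a ground-truth CT is turned into a CBCT-like volume:
#' a global monotone HU miscalibration curve, a radial cupping deficit inside
#' the body, optional streak artifacts and additive Gaussian noise.
#'
#' @param hu_curve strictly increasing function HU -> HU (vectorised), e.g.
#'   from [piecewise_hu_curve()]; the default is the identity.
#' @param cupping_amplitude HU deficit at the body centre relative to the
#'   periphery (>= 0); applied only inside the body mask.
#' @param noise_sigma additive Gaussian HU noise SD inside the body (>= 0).
#' @param streak_count,streak_amplitude number and HU amplitude of linear
#'   in-plane streak artifacts inside the body.
#' @param seed integer seed; all randomness in [degrade_to_cbct()] flows
#'   from it.
#' @return An object of class `degradation_params`.
#' @export
degradation_params <- function(hu_curve = identity, cupping_amplitude = 0,
                               noise_sigma = 0, streak_count = 0,
                               streak_amplitude = 0, seed = 1L) {
  if (!is.function(hu_curve)) stop("`hu_curve` must be a function")
  grid <- seq(-1000, 2000, by = 4)
  vals <- hu_curve(grid)
  if (length(vals) != length(grid) || any(!is.finite(vals)))
    stop("`hu_curve` must be vectorised and finite on [-1000, 2000]")
  if (any(diff(vals) <= 0))
    stop("`hu_curve` must be strictly increasing on [-1000, 2000]")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  if (cupping_amplitude < 0) stop("`cupping_amplitude` must be >= 0")
  structure(list(hu_curve = hu_curve,
                 cupping_amplitude = as.numeric(cupping_amplitude),
                 noise_sigma = as.numeric(noise_sigma),
                 streak_count = as.integer(streak_count),
                 streak_amplitude = as.numeric(streak_amplitude),
                 seed = as.integer(seed)),
            class = "degradation_params")
}

#' Piecewise-linear monotone HU map
#'
#' Builds a vectorised strictly increasing HU -> HU function from knot pairs,
#' linear between knots and linearly extended beyond the end knots with the
#' end-segment slopes.
#'
#' @param hu_in,hu_out numeric knot vectors, `hu_in` strictly increasing,
#'   `hu_out` strictly increasing.
#' @return A function suitable as `hu_curve` in [degradation_params()].
#' @export
piecewise_hu_curve <- function(hu_in, hu_out) {
  stopifnot(length(hu_in) == length(hu_out), length(hu_in) >= 2)
  o <- order(hu_in)
  hu_in <- as.numeric(hu_in[o]); hu_out <- as.numeric(hu_out[o])
  if (any(diff(hu_in) <= 0) || any(diff(hu_out) <= 0))
    stop("knots must be strictly increasing in both HU axes")
  n <- length(hu_in)
  slope_lo <- (hu_out[2] - hu_out[1]) / (hu_in[2] - hu_in[1])
  slope_hi <- (hu_out[n] - hu_out[n - 1]) / (hu_in[n] - hu_in[n - 1])
  function(v) {
    y <- stats::approx(hu_in, hu_out, xout = v, rule = 2)$y
    lo <- v < hu_in[1]; hi <- v > hu_in[n]
    y[lo] <- hu_out[1] + slope_lo * (v[lo] - hu_in[1])
    y[hi] <- hu_out[n] + slope_hi * (v[hi] - hu_in[n])
    y
  }
}

#' Degrade a CT volume into a CBCT-like volume
#'
#' Applies, in order: the global HU miscalibration curve (everywhere), a
#' per-slice radial quadratic cupping deficit (largest at the body centre,
#' zero at the periphery, inside the body mask only), optional streaks, and
#' seeded Gaussian noise inside the body. With all parameters at their null
#' values the output equals the input exactly.
#'
#' @param ct a `ct_volume` in HU.
#' @param params a [degradation_params()].
#' @param body_mask a `ct_mask` (or logical array) on the same grid.
#' @return A `ct_volume`, deterministic given `params$seed`.
#' @export
degrade_to_cbct <- function(ct, params, body_mask) {
  stopifnot(is_volume(ct), inherits(params, "degradation_params"))
  m <- as_mask_array(body_mask, ct)
  out <- ct$values
  if (!identical(params$hu_curve, identity)) {
    out <- array(params$hu_curve(as.numeric(out)), dim = dim(out))
  }
  if (params$cupping_amplitude > 0) {
    sp <- ct$spacing
    for (s in seq_len(dim(out)[1])) {
      sl <- m[s, , ]
      if (!any(sl)) next
      idx <- which(sl, arr.ind = TRUE)
      cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
      r2 <- ((idx[, 1] - cy) * sp[2])^2 + ((idx[, 2] - cx) * sp[3])^2
      rmax2 <- max(r2)
      if (rmax2 == 0) rmax2 <- 1
      deficit <- params$cupping_amplitude * (1 - r2 / rmax2)
      plane <- out[s, , ]
      plane[idx] <- plane[idx] - deficit
      out[s, , ] <- plane
    }
  }
  withr::with_seed(params$seed, {
    if (params$streak_count > 0 && params$streak_amplitude != 0) {
      sp <- ct$spacing
      n2 <- dim(out)[2]; n3 <- dim(out)[3]
      yy <- matrix((seq_len(n2) - 1) * sp[2], n2, n3)
      xx <- matrix((seq_len(n3) - 1) * sp[3], n2, n3, byrow = TRUE)
      field <- matrix(0, n2, n3)
      for (k in seq_len(params$streak_count)) {
        th <- stats::runif(1, 0, pi)
        off <- stats::runif(1, 0.2, 0.8) * max(yy)
        d <- yy * cos(th) + xx * sin(th) - off
        field <- field + ifelse(k %% 2 == 0, 1, -1) *
          params$streak_amplitude * exp(-d^2 / (2 * 1.5^2))
      }
      for (s in seq_len(dim(out)[1])) {
        plane <- out[s, , ]
        plane[m[s, , ]] <- plane[m[s, , ]] + field[m[s, , ]]
        out[s, , ] <- plane
      }
    }
    if (params$noise_sigma > 0) {
      nin <- sum(m)
      out[m] <- out[m] + stats::rnorm(nin, 0, params$noise_sigma)
    }
  })
  volume(out, spacing = ct$spacing, origin = ct$origin)
}

#' Calibration-phantom specification
#'
#' A digital stand-in for a nine-insert electron-density calibration phantom:
#' a water-equivalent cylinder with material insert rods on a ring, each with
#' a known relative electron density and a nominal CT Hounsfield value.
#'
#' The default insert set carries relative electron densities
#' 1.00, 0.20, 0.50, 0.97, 0.99, 1.06, 1.07, 1.16 and 1.61. The matching
#' nominal CT HUs are configurable; defaults map ED monotonically to HU with
#' anchors 0.20 -> -800 (lung), 1.00 -> 0 (water) and 1.61 -> 950 (dense
#' bone), linear in ED between anchors.
#'
#' @param insert_relative_eds relative electron densities, one per insert.
#' @param insert_nominal_hus nominal CT HU per insert; `NULL` uses the
#'   default ED->HU map.
#' @param insert_roi_radius_mm radius of the circular readout ROI.
#' @param body_radius_mm phantom cylinder radius.
#' @param ring_radius_mm radius of the circle on which inserts sit.
#' @param grid_shape,spacing_mm scan grid (axis order slice, row, column).
#' @return An object of class `calibration_phantom_spec`.
#' @export
calibration_phantom_spec <- function(
    insert_relative_eds = c(1.00, 0.20, 0.50, 0.97, 0.99, 1.06, 1.07, 1.16, 1.61),
    insert_nominal_hus = NULL,
    insert_roi_radius_mm = 4,
    body_radius_mm = 80,
    ring_radius_mm = 55,
    grid_shape = c(5, 96, 96),
    spacing_mm = c(3, 2, 2)) {
  eds <- as.numeric(insert_relative_eds)
  if (is.null(insert_nominal_hus))
    insert_nominal_hus <- default_insert_hus(eds)
  hus <- as.numeric(insert_nominal_hus)
  if (length(hus) != length(eds)) stop("one nominal HU per insert required")
  n <- length(eds)
  rod_r <- insert_roi_radius_mm + 3
  # inserts must fit inside the body without overlapping each other
  if (ring_radius_mm + rod_r >= body_radius_mm)
    stop("inserts extend outside the phantom body")
  if (n > 1 && 2 * ring_radius_mm * sin(pi / n) < 2 * rod_r)
    stop("inserts overlap on the ring")
  structure(list(insert_relative_eds = eds, insert_nominal_hus = hus,
                 insert_roi_radius_mm = insert_roi_radius_mm,
                 body_radius_mm = body_radius_mm,
                 ring_radius_mm = ring_radius_mm,
                 rod_radius_mm = rod_r,
                 grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm)),
            class = "calibration_phantom_spec")
}

#' @rdname calibration_phantom_spec
#' @param eds relative electron densities.
#' @export
default_insert_hus <- function(eds) {
  anchors_ed <- c(0.20, 1.00, 1.61)
  anchors_hu <- c(-800, 0, 950)
  round(stats::approx(anchors_ed, anchors_hu, xout = eds, rule = 2)$y)
}

build_calibration_volume <- function(spec) {
  gs <- spec$grid_shape; sp <- spec$spacing_mm
  ctr <- (gs[2:3] - 1) * sp[2:3] / 2
  yy <- matrix((seq_len(gs[2]) - 1) * sp[2], gs[2], gs[3])
  xx <- matrix((seq_len(gs[3]) - 1) * sp[3], gs[2], gs[3], byrow = TRUE)
  r <- sqrt((yy - ctr[1])^2 + (xx - ctr[2])^2)
  plane <- ifelse(r <= spec$body_radius_mm, 0, -1000)
  n <- length(spec$insert_relative_eds)
  centers <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    th <- 2 * pi * (k - 1) / n
    cc <- ctr + spec$ring_radius_mm * c(cos(th), sin(th))
    centers[k, ] <- cc
    rod <- sqrt((yy - cc[1])^2 + (xx - cc[2])^2) <= spec$rod_radius_mm
    plane[rod] <- spec$insert_nominal_hus[k]
  }
  vals <- array(rep(plane, each = gs[1]), dim = gs)
  body <- array(rep(r <= spec$body_radius_mm, each = gs[1]), dim = gs)
  list(vol = volume(vals, spacing = sp), body = body, centers = centers,
       yy = yy, xx = xx)
}

#' Simulate reading out a calibration phantom scan
#'
#' Builds the digital calibration phantom, optionally degrades it with the
#' HU curve and noise of a [degradation_params()] (cupping and streaks are
#' not applied to the phantom scan), and reads the mean HU in a circular ROI
#' at each insert centre in the central slice.
#'
#' @param spec a [calibration_phantom_spec()].
#' @param params a [degradation_params()] for a CBCT-side scan, or `NULL`
#'   for the CT-side scan (readings then equal the nominal HUs exactly).
#' @return A data.frame with columns `relative_ed` and `mean_hu`, one row
#'   per insert, in the order of `spec$insert_relative_eds`.
#' @export
scan_calibration_phantom <- function(spec, params = NULL) {
  stopifnot(inherits(spec, "calibration_phantom_spec"))
  if (spec$ring_radius_mm + spec$insert_roi_radius_mm > spec$body_radius_mm)
    stop("readout ROI extends outside the phantom")
  b <- build_calibration_volume(spec)
  vol <- b$vol
  if (!is.null(params)) {
    stopifnot(inherits(params, "degradation_params"))
    quiet <- degradation_params(hu_curve = params$hu_curve,
                                cupping_amplitude = 0,
                                noise_sigma = params$noise_sigma,
                                seed = params$seed)
    vol <- degrade_to_cbct(vol, quiet, b$body)
  }
  central <- (dim(vol$values)[1] + 1) %/% 2
  plane <- vol$values[central, , ]
  mean_hu <- vapply(seq_len(nrow(b$centers)), function(k) {
    roi <- sqrt((b$yy - b$centers[k, 1])^2 + (b$xx - b$centers[k, 2])^2) <=
      spec$insert_roi_radius_mm
    mean(plane[roi])
  }, numeric(1))
  data.frame(relative_ed = spec$insert_relative_eds, mean_hu = mean_hu)
}

#' Synthetic 3D dose grid as a sum of Gaussian blobs
#'
#' @param shape integer length-3 voxel counts (slice, row, column).
#' @param spacing_mm voxel size in mm per axis.
#' @param blobs list of `list(center_mm=, width_mm=, peak_gy=)`; `width_mm`
#'   is the isotropic Gaussian sigma and must be > 0; peaks must be >= 0.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param noise_sd optional additive Gaussian noise SD in Gy (clamped at 0).
#' @return A nonnegative `ct_volume` in Gy; deterministic given `seed`.
#' @export
generate_dose_grid <- function(shape, spacing_mm = c(3, 3, 3), blobs = list(),
                               seed = 1L, noise_sd = 0) {
  shape <- as.integer(shape)
  vals <- array(0, dim = shape)
  ii <- (seq_len(shape[1]) - 1) * spacing_mm[1]
  jj <- (seq_len(shape[2]) - 1) * spacing_mm[2]
  kk <- (seq_len(shape[3]) - 1) * spacing_mm[3]
  for (bl in blobs) {
    if (bl$width_mm <= 0) stop("blob width must be positive")
    if (bl$peak_gy < 0) stop("blob peak must be nonnegative")
    di <- exp(-(ii - bl$center_mm[1])^2 / (2 * bl$width_mm^2))
    dj <- exp(-(jj - bl$center_mm[2])^2 / (2 * bl$width_mm^2))
    dk <- exp(-(kk - bl$center_mm[3])^2 / (2 * bl$width_mm^2))
    vals <- vals + bl$peak_gy * outer(outer(di, dj), dk)
  }
  if (noise_sd > 0) {
    withr::with_seed(as.integer(seed), {
      vals <- vals + array(stats::rnorm(length(vals), 0, noise_sd), dim = shape)
    })
    vals <- pmax(vals, 0)
  }
  volume(vals, spacing = spacing_mm)
}
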