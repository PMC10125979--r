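#' HU to relative-electron-density calibration curve
#'
#' Builds a piecewise-linear calibration curve from phantom insert readings:
#' the mean HU of each insert plotted against its known relative electron
#' density. Points are sorted by HU; the relative ED must be nondecreasing in
#' HU or construction fails (a non-monotone HU-ED relation is unphysical).
#'
#' @param readings data.frame (or list) with columns/elements `relative_ed`
#'   and `mean_hu`, one row per insert; at least 2 readings with distinct
#'   `mean_hu`.
#' @return An object of class `calibration_curve` with a `points`
#'   data.frame sorted by `mean_hu`.
#' @export
build_curve <- function(readings) {
  hu <- as.numeric(readings$mean_hu)
  ed <- as.numeric(readings$relative_ed)
  if (length(hu) < 2) stop("at least 2 readings are required")
  if (anyDuplicated(hu)) stop("duplicate mean_hu readings")
  o <- order(hu)
  hu <- hu[o]; ed <- ed[o]
  if (any(diff(ed) < 0))
    stop("non-monotone curve: relative_ed decreases with increasing mean_hu")
  structure(list(points = data.frame(mean_hu = hu, relative_ed = ed)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %d points, HU [%g, %g], ED [%g, %g]\n",
              nrow(x$points), min(x$points$mean_hu), max(x$points$mean_hu),
              min(x$points$relative_ed), max(x$points$relative_ed)))
  invisible(x)
}

#' Evaluate a calibration curve
#'
#' Piecewise-linear interpolation between nodes. Outside the node range,
#' `"clamp"` holds the end ED values and `"linear"` extends the end segments.
#'
#' @param curve a [build_curve()] result.
#' @param hu numeric HU values to evaluate at.
#' @param extrapolation `"clamp"` or `"linear"`.
#' @return Relative ED values, same length as `hu`.
#' @export
eval_curve <- function(curve, hu, extrapolation = c("clamp", "linear")) {
  extrapolation <- match.arg(extrapolation)
  p <- curve$points
  y <- stats::approx(p$mean_hu, p$relative_ed, xout = hu, rule = 2)$y
  if (extrapolation == "linear") {
    n <- nrow(p)
    slope_lo <- (p$relative_ed[2] - p$relative_ed[1]) /
      (p$mean_hu[2] - p$mean_hu[1])
    slope_hi <- (p$relative_ed[n] - p$relative_ed[n - 1]) /
      (p$mean_hu[n] - p$mean_hu[n - 1])
    lo <- hu < p$mean_hu[1]; hi <- hu > p$mean_hu[n]
    y[lo] <- p$relative_ed[1] + slope_lo * (hu[lo] - p$mean_hu[1])
    y[hi] <- p$relative_ed[n] + slope_hi * (hu[hi] - p$mean_hu[n])
  }
  y
}

invert_curve <- function(curve, ed, extrapolation = "clamp") {
  p <- curve$points
  if (any(diff(p$relative_ed) <= 0))
    stop("curve is not invertible: relative_ed has a flat (or decreasing) segment")
  y <- stats::approx(p$relative_ed, p$mean_hu, xout = ed, rule = 2)$y
  if (extrapolation == "linear") {
    n <- nrow(p)
    slope_lo <- (p$mean_hu[2] - p$mean_hu[1]) /
      (p$relative_ed[2] - p$relative_ed[1])
    slope_hi <- (p$mean_hu[n] - p$mean_hu[n - 1]) /
      (p$relative_ed[n] - p$relative_ed[n - 1])
    lo <- ed < p$relative_ed[1]; hi <- ed > p$relative_ed[n]
    y[lo] <- p$mean_hu[1] + slope_lo * (ed[lo] - p$relative_ed[1])
    y[hi] <- p$mean_hu[n] + slope_hi * (ed[hi] - p$relative_ed[n])
  }
  y
}

#' Compose a CBCT to CT-equivalent HU correction
#'
#' The correction maps a CBCT HU value to relative ED through the CBCT curve,
#' then back to HU through the inverse of the CT curve:
#' `map(v) = ct_curve^-1(cbct_curve(v))`. At every insert, the CBCT mean HU is
#' mapped exactly to the CT mean HU. The CT curve must be strictly increasing
#' in relative ED (invertible). The composed map is monotone nondecreasing
#' over the clipped HU range.
#'
#' @param cbct_curve,ct_curve [build_curve()] results for the CBCT-side and
#'   CT-side phantom scans.
#' @param extrapolation_mode `"clamp"` (default; end values held outside the
#'   node range) or `"linear"` (end segments extended).
#' @return An object of class `hu_correction_map`; call it on HU values with
#'   [apply_correction()] or via `map$fun(hu)`.
#' @export
compose_correction <- function(cbct_curve, ct_curve,
                               extrapolation_mode = c("clamp", "linear")) {
  extrapolation_mode <- match.arg(extrapolation_mode)
  stopifnot(inherits(cbct_curve, "calibration_curve"),
            inherits(ct_curve, "calibration_curve"))
  if (any(diff(ct_curve$points$relative_ed) <= 0))
    stop("ct_curve is not invertible: relative_ed must be strictly increasing")
  fun <- function(v) {
    ed <- eval_curve(cbct_curve, v, extrapolation = extrapolation_mode)
    invert_curve(ct_curve, ed, extrapolation = extrapolation_mode)
  }
  grid <- seq(-1000, 2000, length.out = 601)
  gv <- fun(grid)
  if (any(diff(gv) < -1e-9))
    stop("composed correction is not monotone nondecreasing on [-1000, 2000]")
  structure(list(cbct_curve = cbct_curve, ct_curve = ct_curve,
                 extrapolation_mode = extrapolation_mode, fun = fun),
            class = "hu_correction_map")
}

#' @export
print.hu_correction_map <- function(x, ...) {
  cat(sprintf("<hu_correction_map> %d CBCT / %d CT nodes, extrapolation '%s'\n",
              nrow(x$cbct_curve$points), nrow(x$ct_curve$points),
              x$extrapolation_mode))
  invisible(x)
}

#' Apply an HU correction map to a CBCT volume
#'
#' Voxelwise application of the composed correction, producing the corrected
#' CBCT (CBCT_cor). If a mask is supplied, voxels outside it pass through
#' unchanged. Grid metadata is preserved.
#'
#' @param cbct a `ct_volume` in HU.
#' @param map an [compose_correction()] result.
#' @param mask optional `ct_mask` or logical array on the same grid.
#' @return A `ct_volume`.
#' @export
apply_correction <- function(cbct, map, mask = NULL) {
  stopifnot(is_volume(cbct), inherits(map, "hu_correction_map"))
  out <- cbct$values
  if (is.null(mask)) {
    out <- array(map$fun(as.numeric(out)), dim = dim(out))
  } else {
    m <- as_mask_array(mask, cbct)
    out[m] <- map$fun(out[m])
  }
  volume(out, spacing = cbct$spacing, origin = cbct$origin)
}

#' Read / write calibration curves as CSV
#'
#' Two-column CSV (`mean_hu`, `relative_ed`) with a one-line header.
#'
#' @param curve a `calibration_curve`.
#' @param path CSV file path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(curve$points[, c("mean_hu", "relative_ed")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  build_curve(df)
}

#' Serialize a correction map as two CSVs plus JSON metadata
#'
#' @param map an `hu_correction_map`.
#' @param dir output directory (created if missing).
#' @export
write_correction_map <- function(map, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_curve_csv(map$cbct_curve, file.path(dir, "cbct_curve.csv"))
  write_curve_csv(map$ct_curve, file.path(dir, "ct_curve.csv"))
  jsonlite::write_json(
    list(extrapolation_mode = map$extrapolation_mode,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(dir, "correction_map.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_correction_map
#' @export
read_correction_map <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "correction_map.json"))
  compose_correction(read_curve_csv(file.path(dir, "cbct_curve.csv")),
                     read_curve_csv(file.path(dir, "ct_curve.csv")),
                     extrapolation_mode = meta$extrapolation_mode)
}
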