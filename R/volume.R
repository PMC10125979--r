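#' 3D scalar volume with grid metadata
#'
#' The universal image currency of the package: a 3D array of values (HU for
#' CT-like images, Gy for dose) plus per-axis voxel spacing and world origin,
#' both in millimetres. Axis order is fixed as (slice, row, column); voxel
#' indices are 0-based in world-coordinate arithmetic, so the centre of voxel
#' `(i, j, k)` lies at `origin + c(i, j, k) * spacing`.
#'
#' @param values 3D numeric array, all values finite.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3, world position (mm) of voxel (0, 0, 0).
#' @return An object of class `ct_volume`.
#' @export
volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!all(is.finite(values)))
    stop("volume values must all be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @rdname volume
#' @param x object to test or print.
#' @export
is_volume <- function(x) inherits(x, "ct_volume")

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm, range [%.1f, %.1f]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$values)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s must share shape, spacing and origin", what))
  invisible(TRUE)
}

#' Binary mask on a volume grid
#'
#' @param values 3D logical array.
#' @param spacing,origin grid metadata, as for [volume()].
#' @return An object of class `ct_mask`.
#' @export
binary_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L || !is.logical(values))
    stop("`values` must be a 3D logical array")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "ct_mask")
}

#' @rdname binary_mask
#' @param x object to test.
#' @export
is_mask <- function(x) inherits(x, "ct_mask")

#' @export
dim.ct_mask <- function(x) dim(x$values)

#' @export
print.ct_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_mask> %d x %d x %d voxels, %d in-mask\n",
              d[1], d[2], d[3], sum(x$values)))
  invisible(x)
}

as_mask_array <- function(mask, vol) {
  if (is_mask(mask)) {
    if (!identical(dim(mask$values), dim(vol$values)))
      stop("mask grid does not match volume grid")
    mask$values
  } else if (is.array(mask) && is.logical(mask)) {
    if (!identical(dim(mask), dim(vol$values)))
      stop("mask grid does not match volume grid")
    mask
  } else stop("mask must be a ct_mask or a logical array")
}

#' Read / write volumes as NIfTI
#'
#' Voxel spacing is carried in the NIfTI pixdim header; the world origin in
#' the sform translation. Axis order on disk follows the in-memory array.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol a [volume()].
#' @return `read_volume()` returns a `ct_volume`; `write_volume()` returns
#'   `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  mat <- diag(4)
  diag(mat)[1:3] <- vol$spacing
  mat[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(mat, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  org <- if (!is.null(xf)) as.numeric(xf[1:3, 4]) else c(0, 0, 0)
  volume(vals, spacing = abs(sp[1:3]), origin = org)
}
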