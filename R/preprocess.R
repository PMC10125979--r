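#' Resample a volume onto a reference grid
#'
#' Trilinear resampling of `moving` onto the grid (shape, spacing, origin) of
#' `reference`, assuming both share one world coordinate frame (rigid
#' alignment is expected to have been done upstream). Voxels that map outside
#' the moving volume are set to -1000 HU. This is how the planning CT becomes
#' the reference RCT on the CBCT grid.
#'
#' @param moving,reference `ct_volume`s in a common world frame.
#' @param outside fill value for out-of-bounds voxels (default -1000).
#' @return A `ct_volume` on the reference grid.
#' @export
resample_to_grid <- function(moving, reference, outside = -1000) {
  stopifnot(is_volume(moving), is_volume(reference))
  if (any(moving$spacing <= 0) || any(reference$spacing <= 0))
    stop("degenerate spacing")
  if (same_grid(moving, reference)) return(moving)
  d <- dim(reference$values)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                               k = seq_len(d[3]) - 1))
  world <- sweep(sweep(idx, 2, reference$spacing, `*`), 2, reference$origin, `+`)
  mv <- sweep(sweep(world, 2, moving$origin, `-`), 2, moving$spacing, `/`)
  vals <- trilinear_sample_cpp(moving$values, mv, outside)
  volume(array(vals, dim = d), spacing = reference$spacing,
         origin = reference$origin)
}

#' Create a body mask by thresholding and morphology
#'
#' Voxels above `threshold_hu` are kept, reduced to the largest 3D connected
#' component (removing the couch, immobilisation devices and other
#' non-anatomical structures), then closed with an ellipsoidal structuring
#' element of radius `closing_radius_mm` and hole-filled slice by slice (so
#' internal air cavities belong to the body).
#'
#' @param vol a `ct_volume` in HU.
#' @param threshold_hu threshold separating body from air (default -400).
#' @param closing_radius_mm morphological closing radius in mm (default 2).
#' @return A nonempty `ct_mask`; an all-air volume is an error.
#' @export
make_body_mask <- function(vol, threshold_hu = -400, closing_radius_mm = 2) {
  stopifnot(is_volume(vol))
  raw <- vol$values > threshold_hu
  if (!any(raw)) stop("empty mask: no voxels above threshold")
  d <- dim(raw)
  m <- largest_component_cpp(as.logical(raw), as.integer(d))
  r_vox <- closing_radius_mm / vol$spacing
  m <- binary_closing_cpp(m, as.integer(d), r_vox[1], r_vox[2], r_vox[3])
  m <- fill_holes_slices_cpp(m, as.integer(d))
  m <- array(m, dim = d)
  if (!any(m)) stop("empty mask after morphological processing")
  binary_mask(m, spacing = vol$spacing, origin = vol$origin)
}

#' Clip HU and flatten the background
#'
#' Clips values to the working HU range [-1000, 2000] and sets every voxel
#' outside the body mask to exactly -1000 HU. Idempotent.
#'
#' @param vol a `ct_volume`.
#' @param mask a `ct_mask` or logical array on the same grid.
#' @return A `ct_volume`.
#' @export
clip_and_flatten <- function(vol, mask) {
  stopifnot(is_volume(vol))
  m <- as_mask_array(mask, vol)
  out <- pmin(pmax(vol$values, -1000), 2000)
  out[!m] <- -1000
  volume(out, spacing = vol$spacing, origin = vol$origin)
}

#' Normalize HU to [-1, 1] (and back)
#'
#' The affine training normalization `n(v) = (v + 1000) / 1500 - 1`, mapping
#' the clipped range [-1000, 2000] onto [-1, 1]; `denormalize_hu()` is its
#' exact inverse.
#'
#' @param hu HU values within [-1000, 2000] (clip first).
#' @param x normalized values within [-1, 1].
#' @return Numeric vector/array of the same shape.
#' @export
normalize_hu <- function(hu) {
  if (any(hu < -1000 - 1e-9 | hu > 2000 + 1e-9, na.rm = TRUE))
    stop("HU outside [-1000, 2000]; clip before normalizing")
  (hu + 1000) / 1500 - 1
}

#' @rdname normalize_hu
#' @export
denormalize_hu <- function(x) {
  if (any(x < -1 - 1e-9 | x > 1 + 1e-9, na.rm = TRUE))
    stop("normalized values outside [-1, 1]")
  (x + 1) * 1500 - 1000
}

#' Center-crop (or pad) a 2D slice
#'
#' Crops a centred `size` x `size` window. When the leftover is odd, the
#' extra row/column is dropped from the high-index side, i.e. the window
#' starts at `floor((n - size) / 2)` (0-based) on each axis. A 410 x 410
#' CBCT slice therefore crops to rows/columns [77, 333) (0-based,
#' half-open). `center_pad()` is the inverse placement, padding with `fill`.
#'
#' @param slice2d 2D matrix, at least `size` on both axes for cropping.
#' @param size output side length (default 256).
#' @param fill padding value for `center_pad()`.
#' @return A `size` x `size` matrix.
#' @export
center_crop <- function(slice2d, size = 256L) {
  d <- dim(slice2d)
  if (is.null(d) || length(d) != 2L) stop("`slice2d` must be a 2D matrix")
  if (any(d < size)) stop("slice smaller than the crop size")
  s1 <- (d[1] - size) %/% 2L
  s2 <- (d[2] - size) %/% 2L
  slice2d[(s1 + 1):(s1 + size), (s2 + 1):(s2 + size), drop = FALSE]
}

#' @rdname center_crop
#' @export
center_pad <- function(slice2d, size = 256L, fill = -1) {
  d <- dim(slice2d)
  if (any(d > size)) stop("slice larger than the pad size")
  out <- matrix(fill, size, size)
  s1 <- (size - d[1]) %/% 2L
  s2 <- (size - d[2]) %/% 2L
  out[(s1 + 1):(s1 + d[1]), (s2 + 1):(s2 + d[2])] <- slice2d
  out
}

#' Patient-level train/validation split
#'
#' Randomly assigns patients to training and validation with no patient in
#' both sets, deterministically under `split_seed`, and reports the slice
#' bookkeeping. With 52 patients, a training fraction of 41/52 and 264
#' slices per patient this reproduces the 41/11 patient split with 10824
#' training and 2904 validation slices.
#'
#' @param patients vector of patient identifiers (length >= 2).
#' @param split_seed integer seed for the random assignment.
#' @param train_fraction fraction of patients assigned to training.
#' @param slices_per_patient slices contributed by each patient
#'   (default 264).
#' @return A list with `train`, `validation` (patient id vectors) and
#'   `counts` (patients and slices per split).
#' @export
build_dataset <- function(patients, split_seed = 1L, train_fraction = 41 / 52,
                          slices_per_patient = 264L) {
  patients <- as.vector(patients)
  n <- length(patients)
  if (n < 2) stop("at least 2 patients are required")
  if (anyDuplicated(patients)) stop("duplicate patient identifiers")
  n_train <- round(train_fraction * n)
  n_train <- max(1L, min(n - 1L, as.integer(n_train)))
  train <- withr::with_seed(as.integer(split_seed),
                            sample(patients, n_train))
  validation <- setdiff(patients, train)
  if (length(intersect(train, validation)) > 0)
    stop("train/validation overlap detected")
  list(train = train, validation = validation,
       counts = list(
         train_patients = length(train),
         validation_patients = length(validation),
         train_slices = length(train) * as.integer(slices_per_patient),
         validation_slices = length(validation) * as.integer(slices_per_patient)))
}

#' Extract normalized training slices from a volume
#'
#' Convenience wrapper chaining the preparation contract: clip/flatten with
#' the body mask, take `n_slices` axial slices evenly spaced through the
#' in-mask extent, normalize to [-1, 1] and center-crop/pad to `size`.
#'
#' @param vol a `ct_volume`.
#' @param mask body `ct_mask`.
#' @param n_slices number of axial slices to take.
#' @param size output slice side length.
#' @return A 3D array `size` x `size` x `n_slices` in [-1, 1], with the
#'   chosen slice indices as attribute `"slices"`.
#' @export
extract_slices <- function(vol, mask, n_slices = 8L, size = 64L) {
  m <- as_mask_array(mask, vol)
  flat <- clip_and_flatten(vol, m)
  has_body <- which(apply(m, 1, any))
  if (length(has_body) == 0) stop("mask is empty")
  picks <- unique(round(seq(has_body[1] + 1, has_body[length(has_body)] - 1,
                            length.out = n_slices)))
  picks <- pmin(pmax(picks, has_body[1]), has_body[length(has_body)])
  out <- array(0, dim = c(size, size, length(picks)))
  for (q in seq_along(picks)) {
    sl <- normalize_hu(flat$values[picks[q], , ])
    d <- dim(sl)
    if (d[1] >= size && d[2] >= size) sl <- center_crop(sl, size)
    else sl <- center_pad(center_crop(sl, min(d, size)), size, fill = -1)
    out[, , q] <- sl
  }
  attr(out, "slices") <- picks
  out
}
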