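#' DVH parameters of a dose grid over a structure
#'
#' Dx is the minimum dose received by the hottest x% of the structure
#' volume, computed from the sorted in-mask voxel doses with linear
#' interpolation between ranks; `dmean` is the arithmetic mean and `dmax`
#' the maximum voxel dose. On clinically smooth dose fields
#' `d98 <= dmean <= d2 <= dmax`.
#'
#' @param dose a `ct_volume` in Gy (nonnegative).
#' @param structure nonempty `ct_mask` (or logical array) on the dose grid.
#' @param label structure label carried into the result.
#' @return List of class `dvh_metrics`: `d2`, `d98`, `dmean`, `dmax`,
#'   `label`, `n_voxels`.
#' @export
dvh_metrics <- function(dose, structure, label = NA_character_) {
  stopifnot(is_volume(dose))
  m <- as_mask_array(structure, dose)
  if (!any(m)) stop("empty structure")
  d <- dose$values[m]
  structure(list(d2 = dose_at_volume(d, 2), d98 = dose_at_volume(d, 98),
                 dmean = mean(d), dmax = max(d), label = label,
                 n_voxels = length(d)),
            class = "dvh_metrics")
}

#' @rdname dvh_metrics
#' @param doses numeric vector of in-structure voxel doses.
#' @param x percent volume (Dx), e.g. 2 for D2.
#' @export
dose_at_volume <- function(doses, x) {
  n <- length(doses)
  s <- sort(doses, decreasing = TRUE)  # s[1] hottest
  if (n == 1) return(s[1])
  # rank position covering x% of volume, linear between ranks
  pos <- 1 + (x / 100) * (n - 1)
  lo <- floor(pos); hi <- ceiling(pos)
  s[lo] + (pos - lo) * (s[min(hi, n)] - s[lo])
}

#' @export
print.dvh_metrics <- function(x, ...) {
  cat(sprintf("<dvh_metrics> %s: D2 %.2f, D98 %.2f, Dmean %.2f, Dmax %.2f Gy (%d voxels)\n",
              x$label, x$d2, x$d98, x$dmean, x$dmax, x$n_voxels))
  invisible(x)
}

#' Relative dosimetric difference in percent
#'
#' `100 * |metric_eval - metric_ref| / metric_ref`.
#'
#' @param metric_eval,metric_ref dose metrics in Gy; `metric_ref > 0`.
#' @return Percent difference (>= 0).
#' @export
relative_dose_difference <- function(metric_eval, metric_ref) {
  if (any(metric_ref <= 0)) stop("reference metric must be positive")
  100 * abs(metric_eval - metric_ref) / metric_ref
}

#' Gamma analysis criteria
#'
#' @param dose_percent dose-difference criterion as percent of the global
#'   normalization dose (3 or 2 in the usual presets).
#' @param dta_mm distance-to-agreement criterion in mm.
#' @param low_dose_threshold_percent reference voxels below this percent of
#'   the normalization dose are excluded (usual preset: 10).
#' @param normalization `"reference_max"` (global maximum of the reference
#'   dose, default) or `"prescription"` (supply `prescription_gy`).
#' @param prescription_gy prescription dose in Gy when
#'   `normalization = "prescription"`.
#' @return List of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_percent = 3, dta_mm = 3,
                           low_dose_threshold_percent = 10,
                           normalization = c("reference_max", "prescription"),
                           prescription_gy = NULL) {
  normalization <- match.arg(normalization)
  if (dose_percent <= 0 || dta_mm <= 0 || low_dose_threshold_percent <= 0)
    stop("gamma criteria must all be positive")
  if (normalization == "prescription" &&
      (is.null(prescription_gy) || prescription_gy <= 0))
    stop("prescription normalization requires a positive prescription_gy")
  structure(list(dose_percent = dose_percent, dta_mm = dta_mm,
                 low_dose_threshold_percent = low_dose_threshold_percent,
                 normalization = normalization,
                 prescription_gy = prescription_gy),
            class = "gamma_criteria")
}

gamma_offsets <- function(dta_mm, search_factor = 2, step_divisor = 10) {
  # all offsets on a cubic lattice of pitch dta/step_divisor within a ball
  # of radius search_factor * dta, sorted by distance (zero offset first)
  step <- dta_mm / step_divisor
  r <- search_factor * dta_mm
  g <- seq(-r, r, by = step)
  off <- as.matrix(expand.grid(g, g, g))
  dimnames(off) <- NULL
  d2 <- rowSums(off^2)
  keep <- d2 <= r^2 + 1e-12
  off <- off[keep, , drop = FALSE]
  off[order(d2[keep]), , drop = FALSE]
}

#' Global 3D gamma pass rate
#'
#' For every reference voxel at or above the low-dose threshold, the gamma
#' index is the minimum over a sub-voxel search neighbourhood of
#' `sqrt((dose difference / dose criterion)^2 + (distance / DTA)^2)`, with
#' the evaluated dose trilinearly interpolated at each search position. The
#' search covers a ball of radius `2 * dta_mm` sampled at `dta_mm / 10`.
#' A voxel passes if gamma <= 1. Grids must be co-registered and identical.
#'
#' @param eval_dose,ref_dose `ct_volume`s in Gy on identical grids.
#' @param criteria a [gamma_criteria()].
#' @param method `"kernel"` (shipped, distance-sorted search with early
#'   termination) or `"brute"` (plain exhaustive enumeration over the same
#'   offsets; an independent reference implementation).
#' @return List of class `gamma_result`: `pass_rate` (percent),
#'   `n_evaluated`, `n_passed`, and `gamma_map` (a `ct_volume`; NA where
#'   below threshold).
#' @export
gamma_pass_rate <- function(eval_dose, ref_dose, criteria = gamma_criteria(),
                            method = c("kernel", "brute")) {
  method <- match.arg(method)
  stopifnot(is_volume(eval_dose), is_volume(ref_dose),
            inherits(criteria, "gamma_criteria"))
  stopifnot_same_grid(eval_dose, ref_dose, "dose grids")
  norm <- if (criteria$normalization == "reference_max")
    max(ref_dose$values) else criteria$prescription_gy
  if (norm <= 0) stop("normalization dose must be positive")
  thresh <- criteria$low_dose_threshold_percent / 100 * norm
  if (!any(ref_dose$values >= thresh))
    stop("all reference voxels are below the low-dose threshold")
  dose_crit <- criteria$dose_percent / 100 * norm
  off <- gamma_offsets(criteria$dta_mm)
  fn <- if (method == "kernel") gamma_map_cpp else gamma_map_brute_cpp
  g <- fn(ref_dose$values, eval_dose$values, ref_dose$spacing, dose_crit,
          criteria$dta_mm, thresh, off)
  g <- array(g, dim = dim(ref_dose$values))
  evaluated <- !is.na(g)
  n_eval <- sum(evaluated)
  n_pass <- sum(g[evaluated] <= 1)
  structure(list(pass_rate = 100 * n_pass / n_eval, n_evaluated = n_eval,
                 n_passed = n_pass,
                 gamma_map = volume(ifelse(is.na(g), -1, g),
                                    spacing = ref_dose$spacing,
                                    origin = ref_dose$origin),
                 criteria = criteria, normalization_gy = norm),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %.1f%%/%g mm (%g%% threshold): %.2f%% pass (%d/%d voxels)\n",
              x$criteria$dose_percent, x$criteria$dta_mm,
              x$criteria$low_dose_threshold_percent,
              x$pass_rate, x$n_passed, x$n_evaluated))
  invisible(x)
}
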