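#' Masked MAE and ME against a reference volume
#'
#' Mean absolute error and mean (signed) error between a test volume and the
#' reference, computed over the voxels of a body mask only, so that couch,
#' immobilisation devices and background play no role.
#'
#' @param test,reference `ct_volume`s on identical grids.
#' @param mask nonempty `ct_mask` (or logical array) on the same grid.
#' @param case_id optional label carried into the report.
#' @return A list of class `quality_report`: `case_id`, `mae`, `me`,
#'   `n_voxels`. Always `mae >= |me|`.
#' @export
compute_mae_me <- function(test, reference, mask, case_id = NA_character_) {
  stopifnot(is_volume(test), is_volume(reference))
  stopifnot_same_grid(test, reference)
  m <- as_mask_array(mask, reference)
  if (!any(m)) stop("empty mask")
  d <- test$values[m] - reference$values[m]
  structure(list(case_id = case_id, mae = mean(abs(d)), me = mean(d),
                 n_voxels = sum(m)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %s: MAE %.2f HU, ME %+.2f HU over %d voxels\n",
              x$case_id, x$mae, x$me, x$n_voxels))
  invisible(x)
}

#' Summarize per-case quality reports as mean +/- SD
#'
#' @param reports list of `quality_report`s.
#' @return data.frame with mean and SD of MAE and ME across cases.
#' @export
summarize_quality <- function(reports) {
  mae <- vapply(reports, `[[`, numeric(1), "mae")
  me <- vapply(reports, `[[`, numeric(1), "me")
  data.frame(metric = c("mae", "me"),
             mean = c(mean(mae), mean(me)),
             sd = c(stats::sd(mae), stats::sd(me)))
}

#' HU line profile through one or more volumes
#'
#' Samples each labelled volume along the straight segment from `start_mm`
#' to `end_mm` (world coordinates) at uniform arc-length steps, by trilinear
#' interpolation. All volumes must contain the full segment.
#'
#' @param volumes named list of `ct_volume`s.
#' @param start_mm,end_mm segment endpoints in mm (length 3, axis order
#'   slice/row/column).
#' @param step_mm sampling step along the segment.
#' @return data.frame of class `profile_trace`: `position_mm` plus one
#'   column per volume label.
#' @export
line_profile <- function(volumes, start_mm, end_mm, step_mm = 1) {
  stopifnot(is.list(volumes), length(volumes) >= 1, !is.null(names(volumes)))
  start_mm <- as.numeric(start_mm); end_mm <- as.numeric(end_mm)
  len <- sqrt(sum((end_mm - start_mm)^2))
  if (len == 0) stop("degenerate segment")
  pos <- seq(0, len, by = step_mm)
  dirv <- (end_mm - start_mm) / len
  pts <- outer(pos, dirv) + matrix(start_mm, length(pos), 3, byrow = TRUE)
  out <- data.frame(position_mm = pos)
  for (lb in names(volumes)) {
    v <- volumes[[lb]]
    vox <- sweep(sweep(pts, 2, v$origin, `-`), 2, v$spacing, `/`)
    d <- dim(v$values)
    if (any(vox < -1e-9) || any(sweep(vox, 2, d - 1, `-`) > 1e-9))
      stop(sprintf("segment exits volume '%s'", lb))
    out[[lb]] <- as.numeric(trilinear_sample_cpp(v$values, vox, NA_real_))
  }
  class(out) <- c("profile_trace", class(out))
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired test on `a - b`. Zero differences are dropped (classical
#' handling). With `n <= 25` remaining pairs and no tied absolute
#' differences the exact null distribution of the positive-rank sum is used
#' (`method = "exact"`); otherwise the normal approximation with tie
#' correction (`method = "approximate"`). The two-sided exact p is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param a,b paired numeric vectors of equal length (>= 5 nonzero
#'   differences required).
#' @return List of class `paired_test_result`: `statistic` (positive-rank
#'   sum W), `p_value`, `n` (pairs used), `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) stop("degenerate input: all differences are zero")
  n <- length(d)
  if (n < 5) stop("fewer than 5 nonzero differences")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= 25) {
    # exact: P(W <= w) and P(W >= w) under the 2^n sign-flip null
    p_le <- stats::psignrank(w, n)
    p_ge <- 1 - stats::psignrank(w - 1, n)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "approximate"
  }
  structure(list(statistic = w, p_value = p, n = n, method = method),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("<wilcoxon signed-rank> W = %g, p = %.6g (n = %d, %s)\n",
              x$statistic, x$p_value, x$n, x$method))
  invisible(x)
}
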