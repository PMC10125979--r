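#' Default cohort degradation for synthetic CBCT studies
#'
#' A piecewise-linear monotone HU miscalibration anchored at the calibration
#' phantom's insert HUs (gain below unity plus a soft-tissue offset), with
#' radial cupping and Gaussian noise. This is the degradation the hybrid
#' pipeline is expected to undo: the calibration step removes the global HU
#' curve, the image translation removes the residual cupping/noise.
#'
#' @param insert_hus nominal insert HUs the curve is anchored at.
#' @param gain slope of the miscalibration (< 1 compresses contrast).
#' @param offset_hu additive HU shift at the anchors.
#' @param cupping_amplitude,noise_sigma see [degradation_params()].
#' @param seed integer seed.
#' @return A [degradation_params()].
#' @export
cohort_degradation <- function(insert_hus = default_insert_hus(
                                 c(1.00, 0.20, 0.50, 0.97, 0.99, 1.06, 1.07,
                                   1.16, 1.61)),
                               gain = 0.85, offset_hu = -120,
                               cupping_amplitude = 40, noise_sigma = 10,
                               seed = 1L) {
  knots <- sort(unique(insert_hus))
  curve <- piecewise_hu_curve(knots, gain * knots + offset_hu)
  degradation_params(hu_curve = curve, cupping_amplitude = cupping_amplitude,
                     noise_sigma = noise_sigma, seed = seed)
}

#' Run the scaled hybrid-superiority study
#'
#' End-to-end desk-scale version of the hybrid pipeline comparison: a cohort
#' of randomly varied head phantoms is degraded into CBCT-like volumes with
#' a shared monotone HU miscalibration; the calibration phantom is "scanned"
#' on both sides and the composed HU correction produces CBCT_cor; two
#' CycleGAN models are then trained with identical settings, one on raw CBCT
#' slices (producing sCT1) and one on corrected slices (sCT2); both are
#' evaluated on held-out phantoms by masked MAE against the ground-truth CT.
#'
#' @param seed integer; drives phantom variation, degradation noise, the
#'   train/held-out split and model initialization.
#' @param n_phantoms cohort size (default 12).
#' @param n_val held-out phantoms (default 3).
#' @param slices_per_phantom axial slices taken per phantom (default 6).
#' @param config a [model_config()]; default is the scaled profile
#'   (64 x 64, 3 residual blocks, 10 epochs, batch 2, lambda 10).
#' @param degradation a [degradation_params()]; default
#'   [cohort_degradation()].
#' @param train_corrected logical; also train the corrected-input pipeline
#'   (sCT2). Set `FALSE` to run only the raw pipeline.
#' @param verbose print progress.
#' @return A list with per-held-out-case masked MAEs (`mae_cbct`,
#'   `mae_cbct_cor`, `mae_sct1`, `mae_sct2`) and their means, plus the two
#'   fitted models and the correction map.
#' @export
run_hybrid_study <- function(seed = 1L, n_phantoms = 12L, n_val = 3L,
                             slices_per_phantom = 6L,
                             config = NULL, degradation = NULL,
                             train_corrected = TRUE, verbose = FALSE) {
  seed <- as.integer(seed)
  if (is.null(config))
    config <- model_config(scaled_profile = TRUE, seed = seed)
  if (is.null(degradation)) degradation <- cohort_degradation(seed = seed)
  size <- config$image_size

  ## cohort ------------------------------------------------------------------
  phantoms <- lapply(seq_len(n_phantoms), function(i)
    generate_head_phantom(random_head_spec(seed * 1000L + i,
                                           grid_shape = c(40, size, size),
                                           spacing_mm = c(3, 3, 3))))
  masks <- lapply(phantoms, phantom_body_mask)
  cbcts <- lapply(seq_len(n_phantoms), function(i) {
    p <- degradation
    p$seed <- seed * 1000L + i
    degrade_to_cbct(phantoms[[i]], p, masks[[i]])
  })

  ## calibration ---------------------------------------------------------------
  cal_spec <- calibration_phantom_spec()
  ct_readings <- scan_calibration_phantom(cal_spec, NULL)
  cb_readings <- scan_calibration_phantom(cal_spec, degradation)
  cmap <- compose_correction(build_curve(cb_readings),
                             build_curve(ct_readings),
                             extrapolation_mode = "linear")
  cbct_cors <- lapply(seq_len(n_phantoms), function(i)
    apply_correction(cbcts[[i]], cmap, masks[[i]]))

  ## split and slice extraction ----------------------------------------------
  split <- build_dataset(seq_len(n_phantoms), split_seed = seed,
                         train_fraction = (n_phantoms - n_val) / n_phantoms,
                         slices_per_patient = slices_per_phantom)
  tr <- split$train; va <- split$validation
  stack <- function(vols, ids) {
    sl <- lapply(ids, function(i)
      extract_slices(vols[[i]], masks[[i]], n_slices = slices_per_phantom,
                     size = size))
    array(unlist(sl), dim = c(size, size, sum(vapply(sl, function(s)
      dim(s)[3], integer(1)))))
  }
  ct_train <- stack(phantoms, tr)
  cb_train <- stack(cbcts, tr)
  cor_train <- stack(cbct_cors, tr)

  eval_pipeline <- function(g_rct) {
    vapply(va, function(i) {
      flat <- clip_and_flatten(cbcts[[i]], masks[[i]])
      res <- translate_volume(flat, g_rct, masks[[i]], image_size = size)
      compute_mae_me(res$sct, clip_and_flatten(phantoms[[i]], masks[[i]]),
                     masks[[i]])$mae
    }, numeric(1))
  }
  eval_pipeline_cor <- function(g_rct) {
    vapply(va, function(i) {
      flat <- clip_and_flatten(cbct_cors[[i]], masks[[i]])
      res <- translate_volume(flat, g_rct, masks[[i]], image_size = size)
      compute_mae_me(res$sct, clip_and_flatten(phantoms[[i]], masks[[i]]),
                     masks[[i]])$mae
    }, numeric(1))
  }
  ref_mae <- function(vols) vapply(va, function(i)
    compute_mae_me(clip_and_flatten(vols[[i]], masks[[i]]),
                   clip_and_flatten(phantoms[[i]], masks[[i]]),
                   masks[[i]])$mae, numeric(1))

  if (verbose) message("training raw-CBCT pipeline (sCT1) ...")
  fit1 <- train_cyclegan(ct_train, cb_train, config, verbose = verbose)
  out <- list(
    seed = seed,
    held_out = va,
    mae_cbct = ref_mae(cbcts),
    mae_cbct_cor = ref_mae(cbct_cors),
    mae_sct1 = eval_pipeline(fit1$models$generators$g_rct),
    fit_raw = fit1, correction_map = cmap)
  if (train_corrected) {
    if (verbose) message("training corrected-CBCT pipeline (sCT2) ...")
    fit2 <- train_cyclegan(ct_train, cor_train, config, verbose = verbose)
    out$mae_sct2 <- eval_pipeline_cor(fit2$models$generators$g_rct)
    out$fit_cor <- fit2
  }
  out$summary <- data.frame(
    image = c("CBCT", "CBCT_cor", "sCT1",
              if (train_corrected) "sCT2"),
    mean_mae_hu = c(mean(out$mae_cbct), mean(out$mae_cbct_cor),
                    mean(out$mae_sct1),
                    if (train_corrected) mean(out$mae_sct2)))
  out
}
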