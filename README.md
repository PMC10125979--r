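# cyclesct

Hybrid CBCT-to-synthetic-CT pipeline for adaptive radiotherapy, in R.

Cone-beam CT (CBCT) acquired on the treatment machine is readily available
during a radiotherapy course, but its Hounsfield units (HU) are distorted by
scatter — cupping, streaks, and a global intensity miscalibration — so it
cannot be used directly for dose recalculation. `cyclesct` implements a
two-stage correction:

1. **Phantom HU calibration.** HU-to-relative-electron-density curves are
   built from a nine-insert calibration phantom scanned on both the planning
   CT and the CBCT; their composition
   `map(v) = CT⁻¹(CBCT(v))` maps CBCT HU onto CT-equivalent HU
   (piecewise-linear, exact at the insert nodes), producing the corrected
   CBCT (CBCT_cor).
2. **Unpaired image translation.** A 2D CycleGAN — two ResNet generators,
   two patch discriminators, least-squares adversarial losses
   `L = L_CT + L_CBCT + λ(L_fw + L_bw)` with L1 cycle-consistency and
   λ = 10 — translates CBCT (or CBCT_cor) slices into CT-like images (sCT).
   The networks, including backpropagation, are implemented in the package
   on small Rcpp convolution kernels; no deep-learning framework is
   required.

The evaluation stack used to judge such pipelines ships alongside: masked
MAE/ME, HU line profiles, DVH parameters (D2, D98, Dmean, Dmax), global 3D
gamma analysis (3%/3 mm and 2%/2 mm with 10% threshold, sub-voxel search),
and exact Wilcoxon signed-rank tests. A synthetic-data module (digital head
phantoms, CBCT degradation, calibration phantom, Gaussian dose blobs) makes
everything runnable end-to-end with no external data. Intended users are
medical-physics researchers prototyping CBCT correction and evaluation
workflows.

## Worked example

Simulate a head phantom, degrade it into a CBCT, calibrate, and evaluate:

```r
library(cyclesct)

ph   <- generate_head_phantom(phantom_spec())      # ground-truth CT, 40x64x64
mask <- phantom_body_mask(ph)

deg  <- cohort_degradation(noise_sigma = 20, cupping_amplitude = 0, seed = 7)
cbct <- degrade_to_cbct(ph, deg, mask)

cal      <- calibration_phantom_spec()
ct_curve <- build_curve(scan_calibration_phantom(cal, NULL))
cb_curve <- build_curve(scan_calibration_phantom(cal, deg))
map      <- compose_correction(cb_curve, ct_curve, extrapolation_mode = "linear")
cor      <- apply_correction(cbct, map, mask)

compute_mae_me(cbct, ph, mask)
#> <quality_report> NA: MAE 146.66 HU, ME -146.17 HU over 47528 voxels
compute_mae_me(cor, ph, mask)
#> <quality_report> NA: MAE 17.60 HU, ME +1.58 HU over 47528 voxels
```

The calibration removes the global miscalibration (~147 HU of mean absolute
error down to the ~18 HU noise floor). The full desk-scale comparison —
training one CycleGAN on raw CBCT slices (sCT1) and one on corrected slices
(sCT2) over a 12-phantom cohort — runs in a few minutes on one CPU:

```r
st <- run_hybrid_study(seed = 1)
st$summary
#>      image mean_mae_hu
#> 1     CBCT   167.39268
#> 2 CBCT_cor    25.65443
#> 3     sCT1   126.80569
#> 4     sCT2    25.59462
```

The ordering — raw CBCT worst, translation improves it (sCT1), and the
corrected-input pipeline best (sCT2) — is the hybrid-superiority mechanism
the pipeline is built around.

A thin CLI covers the file-in/file-out operations
(`exec/cyclesct simulate phantom`, `calibrate correct`, `evaluate gamma`,
... — see the header of `exec/cyclesct`).

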