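---
title: "Hybrid HU calibration and CycleGAN synthetic CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid HU calibration and CycleGAN synthetic CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cyclesct)
```

## The problem

Cone-beam CT (CBCT) acquired on the treatment machine is the natural image
source for adaptive radiotherapy, but its Hounsfield units are unreliable:
scatter produces cupping, streaks and a global intensity miscalibration, so
dose calculated on raw CBCT is wrong and structures are hard to delineate.
`cyclesct` implements a hybrid correction pipeline: a classical
phantom-based HU calibration first removes the global intensity error, and a
2D CycleGAN then translates the corrected CBCT slices into CT-like images
(synthetic CT, sCT). The package also ships the full evaluation stack used
to judge such pipelines — masked MAE/ME, HU line profiles, DVH parameters,
global 3D gamma analysis, and Wilcoxon signed-rank comparisons — plus a
synthetic-data module (digital head phantoms, a nine-insert calibration
phantom, CBCT degradation, Gaussian dose blobs) so the whole pipeline runs
end-to-end with no external data.

Throughout, volumes are 3D arrays in axis order (slice, row, column) with
per-axis spacing in mm; voxel indices are 0-based in world-coordinate
arithmetic; crop windows are half-open. HU are clipped to [-1000, 2000].

## Phantom HU calibration

A calibration phantom carries inserts of known relative electron density
(defaults: 1.00, 0.20, 0.50, 0.97, 0.99, 1.06, 1.07, 1.16, 1.61). Scanning
it on the planning CT and on the CBCT yields two piecewise-linear HU-to-ED
curves; the correction is their composition

\[ \mathrm{map}(v) \;=\; \mathrm{CT}^{-1}\big(\mathrm{CBCT}(v)\big), \]

which maps every CBCT insert mean exactly onto the matching CT insert mean
and interpolates linearly between nodes — the standard clinical HU-ED table
convention. The CT curve must be strictly increasing in ED to be invertible;
inversion is exact per-segment (axes swapped), not numeric root finding.
Outside the insert range two extrapolation modes exist: `"clamp"` (default;
end ED values held, preventing unphysical densities from extreme HU) and
`"linear"` (end segments extended). Air lies below the lowest insert HU, so
full-range recovery experiments use `"linear"`; the mode is recorded in the
serialized correction map. The measured insert HUs of any particular scanner
are not built in: nominal CT-side HUs default to a monotone ED-to-HU map
anchored at lung (0.20, -800 HU), water (1.00, 0 HU) and dense bone
(1.61, 950 HU), and are configurable.

## The CycleGAN

Two generators translate between the CBCT and CT domains
(`g_rct`: CBCT → sCT; `g_cbct`: CT → sCBCT) and two patch discriminators
with sigmoid outputs in [0, 1] judge each domain. Training minimizes
least-squares adversarial losses

\[ L_{CT} = \mathbb{E}\big[(1 - D_{RCT}(RCT))^2\big]
          + \mathbb{E}\big[D_{RCT}(G_{RCT}(CBCT))^2\big] \]

(and symmetrically \(L_{CBCT}\)), plus L1 cycle-consistency losses
\(L_{fw}, L_{bw}\) on both reconstruction paths, combined as

\[ L = L_{CT} + L_{CBCT} + \lambda\,(L_{fw} + L_{bw}), \qquad \lambda = 10 . \]

There is no identity-mapping term. The full-scale recipe is: 256 × 256
slices, 9 residual blocks, batch 2, 100 epochs, Adam at 2e-4 with both
momentum terms 0.5 and linear decay to zero starting after epoch 20. The
momentum pair (0.5, 0.5) is unusual for Adam's second moment; it is honoured
as the default, and the conventional 0.999 can be set explicitly — the two
are never swapped silently.

Because no deep-learning framework is assumed, the networks are built on
the package's own convolution kernels (im2col + BLAS gemm, with a direct
shifted-submatrix path for large low-channel layers) with hand-derived
backpropagation for every layer (instance norm, reflection padding,
transposed convolutions as zero-stuffed convolutions). All backward passes
are verified against central finite differences in the test suite. Training
is fully seeded and single-threaded deterministic.

### The generator head and the desk-scale profile

`model_config(scaled_profile = TRUE)` is the CPU-scale preset used by the
synthetic experiments: 64 × 64 slices, 3 residual blocks, 12 base channels,
10 epochs (decay from epoch 2), initial learning rate 1e-3. The raised
learning rate compensates for running roughly two orders of magnitude fewer
optimization steps than the full recipe; 2e-3 was observed to diverge, and
the full profile keeps 2e-4.

The generator output head is a gated bounded residual,

\[ y = x + \tfrac{1}{2}(1 - x^2)\,\tanh(f(x)), \]

with the last convolution of \(f\) initialized to zero. For \(|x| \le 1\)
this is analytically confined to \([-1, 1]\), fixes the endpoints (air stays
air), and makes the generator the exact identity at initialization, so
translation starts from its input and learns corrections rather than
resynthesizing images from noise. At a few hundred optimization steps a
conventional tanh head leaves a reconstruction floor of roughly 135 HU —
far above the ~26 HU error of calibration-corrected input — which would
invert the very mechanism the hybrid pipeline is about; the identity-at-init
head removes that artefact of the small step budget. At full scale the
choice is conservative: it changes the parameterization, not the objective.

Whether 410 × 410 clinical slices should be resized or only cropped to the
model size is left to the caller; both `center_crop()` and `center_pad()`
follow the documented convention (extra voxel on the high-index side).

## Synthetic data

The head phantom is a stack of ellipsoids painted into a -1000 HU
background: body soft tissue (~30 HU), a skull shell (~700 HU), brain,
air cavities (-1000 HU) and a low-contrast lesion — the tissue classes a
profile line through a head traverses. Components must nest inside the body;
partially overlapping components with contradictory HU are rejected by name.
`random_head_spec()` jitters geometry coherently (one per-axis anatomy scale,
extra jitter for the small inner structures) to emulate inter-patient
variation.

CBCT degradation applies, in order: a strictly increasing global HU curve
(the miscalibration the calibration step must undo; the cohort default is
piecewise-linear through the insert HUs with gain 0.85 and offset -120 HU),
a per-slice radial quadratic cupping deficit inside the body (default
40 HU at the centre — the simplest smooth field with the right qualitative
shape), optional streaks, and seeded Gaussian noise (default 10 HU). The
calibration-phantom scan applies only the HU curve and noise, so insert
readings equal curve(nominal) up to noise-of-mean. Dose grids are sums of
isotropic 3D Gaussian blobs — smooth, nonnegative, deterministic.

What the generator does *not* emulate: projection-domain physics (no Monte
Carlo scatter, no reconstruction artifacts with realistic texture), organ
deformation between CT and CBCT, and truncated fields of view. Passing
tests therefore demonstrate the pipeline's mechanics and internal
consistency, not clinical-grade performance on patient data.

## Evaluation instruments

* **Masked MAE/ME** are computed over the body mask only, per volume, then
  summarized as mean ± SD across cases. `mae >= |me|` always.
* **Body masks** come from thresholding at -400 HU (configurable), largest
  3D connected component, 2 mm closing and slice-wise hole filling, so
  internal cavities count as body.
* **DVH metrics**: \(D_x\) is the minimum dose to the hottest \(x\%\) of the
  structure, from sorted voxel doses with linear interpolation between
  ranks; `d98 <= dmean <= d2 <= dmax` on smooth fields (heavy-tailed
  pathological fields can break the mean inequality; the package computes
  honestly and does not enforce it).
* **Gamma analysis**: for each reference voxel at or above 10% of the
  normalization dose (global reference maximum by default; prescription
  selectable), the gamma index is minimized over a ball of radius
  2 × DTA sampled at DTA/10, with the evaluated dose trilinearly
  interpolated at each search position. The shipped kernel visits offsets
  sorted by distance and terminates early once the distance term alone
  exceeds the running minimum — an exact optimization; an independent
  plain-enumeration implementation is kept for equivalence testing, and the
  two agree voxel-for-voxel. The search radius/step choice makes the
  oracle equivalence exact at the sampled resolution with bounded
  truncation error. Swapping reference and evaluation is intentionally
  asymmetric, as in any gamma implementation.
* **Wilcoxon signed-rank**: zero differences dropped (classical handling);
  exact two-sided p from the signed-rank null when n ≤ 25 without ties
  (`min(1, 2 min(P(W ≤ w), P(W ≥ w)))`), otherwise the normal approximation
  with tie correction. The exact branch is validated against full \(2^n\)
  enumeration.

## The desk-scale hybrid experiment

`run_hybrid_study()` reproduces the pipeline comparison end-to-end on
synthetic data: 12 random head phantoms (64 × 64 in-plane, 3 mm voxels)
share one degradation; the digital calibration phantom is scanned on both
sides and the composed correction produces CBCT_cor; two CycleGANs with
identical settings are trained, one on raw CBCT slices (sCT1) and one on
corrected slices (sCT2); 9 phantoms train, 3 are held out, 6 axial slices
per phantom, and held-out masked MAE against the ground-truth CT is
reported for CBCT, CBCT_cor, sCT1 and sCT2. Problem sizes were fixed by
profiling single optimization steps on one CPU so a three-seed study
completes in minutes; they are stated here as the package's chosen study
conditions. With the default degradation the expected ordering is
MAE(CBCT) > MAE(sCT1) and median MAE(sCT2) ≤ median MAE(sCT1) over seeds —
the hybrid-superiority mechanism at desk scale. Clinical magnitudes
(hundreds of HU on real anatomy, GPU-scale training) are out of reach of
this profile by design.

```{r, eval = FALSE}
st <- run_hybrid_study(seed = 1)
st$summary
```

## Numerical choices and degenerate inputs

* Normalization is the exact affine map \((v + 1000)/1500 - 1\) with an
  exact inverse; inputs outside the clipped range are errors, not silent
  clamps.
* Curve construction rejects duplicate HU readings and ED that decreases
  with HU; composing with a flat-ED CT curve is a not-invertible error.
* `degrade_to_cbct` with all-null parameters is bit-identical to its input.
* Empty masks, all-air volumes, all-zero dose (no voxel above threshold)
  and all-zero paired differences raise errors rather than returning NaN.
* Resampling uses trilinear interpolation with -1000 fill; at exact grid
  coincidence it returns the input unchanged.
* All simulation randomness flows through explicit per-call seeds
  (`withr::with_seed`); nothing depends on the global RNG state.

## Known limitations

* 2D slice model only; no 3D generator.
* Rigid registration is consumed, not produced: volumes are assumed
  pre-aligned, and gamma v1 requires co-registered identical grids
  (resample first otherwise).
* DICOM series reading is not implemented in this version; NIfTI is the
  interchange format (CSV/JSON for curves and reports).
* The synthetic degradation model is intensity-level, not physics-level;
  conclusions about real scanners require real calibration scans.
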