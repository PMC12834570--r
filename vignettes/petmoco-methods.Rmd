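---
title: "Motion correction and flow quantification for dynamic cardiac PET: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion correction and flow quantification for dynamic cardiac PET: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petmoco)
```

## The problem

Dynamic cardiac PET acquires a rapid sequence of 3D frames after tracer
injection and fits a kinetic model to regional time–activity curves (TACs)
to quantify myocardial blood flow (MBF) and flow reserve (MFR = stress/rest
MBF). Patient motion between frames — most prominently the slow apical–basal
"creep" of the heart in the early post-stress frames — displaces the
myocardium relative to the segmentation derived from the late, stable part of
the scan. Early frames carry the bolus information that anchors the kinetic
fit, so even a few millimetres of early-frame motion propagates into
substantial MBF error. Manual frame-by-frame correction fixes this but takes
an expert several minutes per study and varies between operators.

`petmoco` implements the full experimental loop at desk scale:

1. a **4D digital cardiac phantom** with known kinetics, geometry, and
   ground-truth motion;
2. **per-frame rigid translation simulation**, including bootstrap
   resampling of operator corrections and a parametric creep generator;
3. a **dual-input 3D residual convolutional regressor** that predicts the
   per-frame correction vector against a summed-late-frame reference;
4. a **classical intensity-based registration baseline** (exhaustive masked
   NCC search);
5. **one-tissue-compartment kinetic modelling** of MBF/MFR; and
6. the **evaluation statistics** used in this literature (per-axis
   translation errors, Bland–Altman, Lin's CCC, Fisher-z CCC comparison,
   Pitman–Morgan, DeLong).

## Conventions

Frames are 3D arrays ordered `(x, y, z)` with millimetre spacing; x, y, z
correspond to the septal–lateral, anterior–inferior, and apical–basal axes.
A `motion_trace` stores, per frame, the **correction** `(tx, ty, tz)` in mm —
the translation added to a frame to align it with the reference. The
corrupting displacement is its inverse; a synthetic frame displaced by `d`
therefore carries the training target `-d`. The reference volume is the sum
of frames starting at or after 120 s, when uptake is stable and motion is
least; all frames, including those that feed the reference, are individually
corrected.

## The phantom

The phantom is deliberately geometric rather than anatomical: an ellipsoidal
LV blood cavity (default semi-axes 9×9×12 mm) inside a myocardial shell of
constant 7 mm wall thickness, an adjacent RV blood cavity, and low-uptake
background on a 48³ grid of 2 mm voxels. Every voxel belongs to exactly one
region, and the myocardium is split into 6 angular segments about the LV
long axis (a full 17-segment model would be geometrically meaningless at
this scale). The default grid leaves 25 mm of clearance around the heart so
translations up to the registration search radius never clip it.

The arterial input is a gamma-variate bolus (peak 25 s after a 10 s delay,
shape 3) with a small recirculation tail; regional TACs follow the kinetic
model below; frames are blurred with a 6 mm FWHM Gaussian PSF (a typical
reconstructed cardiac PET resolution) and corrupted with Gaussian noise of
variance proportional to local intensity — a reconstruction-domain surrogate
for Poisson counting noise that permits the negative voxels real
reconstructions contain. The default acquisition schedule is 12×10 s,
6×20 s, 6×60 s (24 frames, 10 min): short early frames to resolve the bolus
and over two minutes of late frames for the reference.

What the phantom does **not** emulate: anatomy (papillary muscles, liver,
lungs), attenuation and scatter, sinogram-domain noise correlations,
cardiac/respiratory gating, rotations or non-rigid motion. Passing tests
demonstrate that the algorithms are correct and that the pipeline responds
to motion as expected — not that clinical accuracy figures transfer.

## Motion simulation

The corpus generator emulates a multi-site population: heart position and
size jitter, resting K1 varying 0.7–1.1 ml/g/min, hyperaemic reserve 1.8–2.6,
about a third of cases with one hypoperfused segment (halved stress flow).
Each scan receives creep motion
`z(t) = A exp(-t_mid / tau)` with case-specific amplitude (|N(6, 3)| mm at
stress, |N(2.5, 1.5)| at rest, capped at 15 mm) and time constant
`tau ~ U(60, 140) s`, in-plane components scaled by 0.4, plus 0.3 mm
per-frame jitter. These defaults give whole-scan average |z| motion of
roughly 1–3 mm with early-frame maxima of 6–15 mm, z-dominant over x and y —
the magnitudes and anisotropy reported for manual corrections of stress
dynamic PET.

The bootstrap augmentation treats observed per-frame corrections as an
empirical distribution: for every frame index and axis, new values are drawn
with replacement from the pool of observed corrections at that frame, which
preserves the temporal structure (large early z, small late everything).
Axes are resampled independently by default — per-frame marginals are what
the observed data constrain — with joint tuple resampling available since
either reading of the original procedure is defensible. Sampled vectors are
not rounded to 1 mm: operators work in integer millimetres, but the
augmented corpus benefits from continuous coverage and the regressor is
continuous anyway. An augmented variant composes with the case's own
correction: the frames are additionally displaced by the inverse of the
sampled trace and the target becomes (operator correction + sampled trace).

## The translation regressor

The network takes two channels — the preprocessed moving frame and the
preprocessed reference — through a weight-shared convolutional stem
(two stride-2 3³ convolutions), concatenates the feature maps, mixes them
with a 1×1 convolution, refines them with residual blocks, downsamples once
more, and maps the flattened coarse feature grid through a fully connected
head to `(tx, ty, tz)` in mm. Flattening rather than global average pooling
is deliberate: average pooling is translation-invariant and would discard
exactly the spatial information a translation regressor needs. The
normalised frame number is appended to the head input by default; it carries
the temporal motion prior, which is the only usable signal in pre-bolus
frames that contain essentially no counts.

Preprocessing resamples both volumes to a 32³ grid spanning the original
field of view, centred on the reference intensity centroid, and scales each
volume to [0, 1] by its own 99.9th-percentile robust maximum — making
predictions invariant to the orders-of-magnitude intensity differences
across dynamic frames.

Training minimises mean squared error on the millimetre vectors (Huber
selectable) with Adam (lr 1e-3, batch 8) over seeded shuffled minibatches;
every frame of every (augmented) scan is an independent sample. The default
desk-scale architecture (8 base channels, one residual block per stage, 32³
input, 8 epochs) has ~45k parameters and trains on a 2 880-sample corpus in
a few minutes on one CPU; depth, width, grid, loss, and the frame-index
input are all configuration fields, since the reference clinical
architecture is necessarily larger. Training covers both rest and stress
scans with phase-specific bootstrap samplers: the frame-index prior differs
sharply between phases (stress creep is several times larger), and a model
trained on one phase systematically over-corrects the other. Weight-sharing of the two stems is the
default (the two inputs are the same modality); separate stems are a config
switch. Site-wise grouped 5-fold cross-validation (`split_by_site`,
`crossval_evaluate`) assigns whole sites to folds — greedy largest-first with
a refinement pass — so no site contributes to both training and test sets.

## The classical baseline

The non-learning baseline registers each frame to the reference by
exhaustive search over integer millimetre translations within ±25 mm,
maximising normalized cross-correlation over an optional mask (a myocardial
segmentation approximates the contour weighting clinical systems use). A
4→2→1 mm coarse-to-fine schedule keeps it tractable; ties break toward the
smallest correction. Frames whose total activity falls below 2% of the
median frame total are skipped with zero correction — registering a
pre-bolus frame of pure noise produces arbitrary vectors. Because early
bolus frames look nothing like the uptake-dominated reference, the NCC
optimum for an *unmoved* early frame can sit a millimetre or two away from
zero; this spurious-correction artifact of intensity-based frame-to-
reference registration is a known limitation of such baselines and one
reason learned correction is attractive. This is an intensity-based
stand-in for contour-model registration, not a reproduction of any vendor
algorithm.

## Kinetics

The one-tissue (two-compartment) model links blood input to tissue activity:

$$C_t(t) = (1 - f_v)\,K_1 \int_0^t e^{-k_2 (t-\tau)} C_a(\tau)\, d\tau + f_v\, C_a(t)$$

with uptake `K1` (ml/g/min), washout `k2` (1/min) and fractional blood
volume `fv`. The convolution is evaluated by an exact-trapezoid recursion on
the TAC grid (second-order accurate, verified against the analytic boxcar
solution). Fitting is bounded weighted least squares (L-BFGS-B, frame-
duration weights) with three fixed physiological starts plus seeded random
restarts; the best residual sum of squares wins and the convergence flag
reports the optimizer's own status. MBF is reported as the fitted `K1`, with a hook for a user-supplied
extraction-fraction correction — the tracer-specific extraction and
spillover terms of the full clinical model are deliberately out of scope.
The blood input is extracted from the eroded core of the LV cavity (4 mm
erosion by default) of the (corrected) series: sampling the full cavity at
PET resolution contaminates the input with myocardial spill-in badly enough
to destabilise the fit, and a small central ROI is the standard clinical
defence. Motion still corrupts the input function exactly as it does
clinically. The residual partial-volume underestimation of absolute K1 is
common to all correction arms, so arm comparisons remain meaningful.
A simplified residual-activity correction subtracts the decay-extrapolated
rest-study tail image from the stress frames.

## Numerical choices and degenerate inputs

* mm→voxel conversion honours anisotropic spacing; trilinear interpolation
  handles subvoxel shifts, nearest-neighbour is exact for integer-voxel
  shifts; out-of-grid voxels are zero-filled and tests restrict themselves
  to interior voxels. A ±half-voxel trilinear round trip is algebraically a
  `[0.25, 0.5, 0.25]` separable smoothing; its error on sharp edges is an
  interpolation property, not a bug, and is tested against that exact
  kernel.
* The Gaussian PSF uses zero padding with a unit-sum kernel, so interior
  activity is conserved; sum checks use a zero background.
* NCC ties (identical scores within 1e-12) break toward the smaller
  Euclidean norm, then lexicographically; constant frames are rejected
  (undefined NCC); all-zero references are rejected in preprocessing.
* Lin's CCC uses population (1/n) moments per the original definition; its
  CI uses the Fisher z-transform with the standard asymptotic SE. The
  per-axis translation error implements the averaged absolute per-frame
  deviation (the formula printed in this literature), with true RMSE also
  reported, as the two are often conflated.
* In the Pitman–Morgan test, an exactly zero covariance between pair sums
  and differences (e.g. `b = -a`) means exactly equal variances and returns
  `t = 0, p = 1`; only fully constant input is rejected.
* DeLong AUC orients scores so that higher indicates disease; flow-based
  scores use `orientation = "lower"` since flows fall in disease. A paired
  AUC difference with zero sampling variance returns `p = 1` with a flag.
* All randomised operations take explicit seeds; one master seed drives
  every pipeline stage through deterministic child seeds, and training is
  bitwise reproducible under a fixed seed and thread count.

## Problem sizes

The package's experiments are sized for a single CPU: the standard phantom
is 48³×24 frames; the network experiment trains on 30 rest/stress studies
(augmented ×3, 5 760 samples, 4 epochs at 32³ — with this much data the
loss plateaus within a few epochs) and evaluates 10 held-out rest/stress
pairs; the registration checks run 20 random displacements against
single-resolution exhaustive search; kinetic calibration uses 200 noise
replicates; statistic calibration uses 2 000 simulations. The
`run_pipeline()` defaults are smaller still (6 training studies, 4 epochs)
to make an end-to-end run a coffee-break affair; all sizes are configuration.

## Known limitations

* Translations only — rotations, non-rigid deformation and intra-frame
  motion are out of scope by design.
* The phantom's simple geometry makes registration easier than clinical
  data; the reported recovery rates are upper bounds on clinical behaviour.
* MBF = K1 ignores extraction-fraction saturation at high flows, so
  phantom "MBF" values are interpretable relative to each other, not as
  absolute clinical flows.
* The desk-scale network is orders of magnitude smaller than a clinical
  3D-ResNet; it demonstrates that the training scheme works, not the
  accuracy ceiling of the approach.
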