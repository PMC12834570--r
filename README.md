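# petmoco

Frame-by-frame rigid motion correction for dynamic cardiac PET, and its
downstream effect on myocardial blood flow (MBF) and flow reserve (MFR)
quantification — implemented end to end on a built-in 4D cardiac phantom
with known ground-truth motion.

## The problem

Dynamic PET myocardial perfusion imaging fits a kinetic model to regional
time–activity curves to estimate MBF and MFR. Inter-frame patient motion —
typically a slow apical–basal "creep" of the heart in the early post-stress
frames — misaligns the early bolus frames with the myocardial segmentation
derived from the late, stable frames, and biases the fitted flows. Manual
frame-by-frame correction is accurate but slow and operator-dependent.

`petmoco` provides:

* a **digital cardiac phantom** (`phantom_spec`, `build_phantom`,
  `render_series`, `simulate_corpus`) generating multi-site rest/stress
  dynamic studies with known kinetics and motion;
* **motion simulation** (`creep_trace`, `apply_motion`) and **bootstrap
  augmentation** of per-frame operator corrections (`fit_sampler`,
  `sample_traces`), preserving the temporal structure of motion;
* a **dual-input 3D residual convolutional regressor**
  (`build_regressor`, `train_regressor`, `predict_trace`) that predicts the
  per-frame correction vector $(t_x, t_y, t_z)$ in mm against a
  summed-late-frame reference, with site-wise grouped cross-validation
  (`split_by_site`, `crossval_evaluate`);
* a **classical registration baseline** (`register_translation`,
  `correct_series_classic`): exhaustive masked NCC search over ±25 mm in
  1 mm steps, coarse-to-fine;
* **kinetic quantification** via the one-tissue compartment model

  $$C_t(t) = (1-f_v)\,K_1 \int_0^t e^{-k_2(t-\tau)} C_a(\tau)\,d\tau + f_v\,C_a(t)$$

  (`model_tac`, `fit_one_tissue`, `fit_segments`, `flow_summary`,
  `residual_activity_correct`), reporting MBF as the fitted $K_1$ and
  MFR as stress/rest;
* the **evaluation statistics** of this literature (`translation_error`,
  `bland_altman`, `lins_ccc`, `compare_ccc`, `pitman_morgan`, `auc_delong`,
  `delong_compare`).

Data formats: 4D NIfTI-1 + JSON timing sidecar for series, NIfTI labels for
masks, CSV for traces and correction tables, YAML for configuration. A thin
CLI lives at `inst/cli/petmoco` (`simulate`, `train`, `predict`,
`classic-mc`, `flow`, `evaluate`, `agree`, `crossval`, `run`).

## Worked example

```r
library(petmoco)

# a noisy stress study with 8 mm early-frame creep
st  <- phantom_study(phantom_spec(noise_scale = 0.5), seed = 11)
gt  <- creep_trace(default_schedule(), 8, decay_s = 100, xy_scale = 0.4,
                   jitter_sd_mm = 0.3, seed = 12)
bad <- apply_motion(st$series, invert_trace(gt))

# classical correction
cl <- correct_series_classic(bad, mask = st$phantom$masks$myocardium)
translation_error(gt, cl$trace)
#> translation error over 24 frames (mm):
#>             x     y     z
#> average 0.711 0.398 1.443
#> max     2.600 2.736 7.829
#> rmse    0.859 0.682 1.990

# motion biases the fitted segmental uptake; correction recovers it
k1 <- function(s) sapply(fit_segments(s, st$phantom, seed = 1), `[[`, "K1")
round(100 * abs(k1(bad)         - k1(st$series)) / k1(st$series), 1)
#> seg1 seg2 seg3 seg4 seg5 seg6
#> 16.5 14.4  8.9 21.2 18.2  3.3
round(100 * abs(k1(cl$corrected) - k1(st$series)) / k1(st$series), 1)
#> seg1 seg2 seg3 seg4 seg5 seg6
#>  1.4  3.3  8.1  7.9  2.6  2.9
```

The 7.8 mm max z error sits on the near-empty pre-bolus frame, which the
baseline deliberately skips (registering pure noise is worse than doing
nothing). The corrupted study mis-estimates segmental $K_1$ by up to ~21%;
after classical correction the maximal bias halves and most segments drop
below 5%. Training the
regressor on a simulated corpus follows the same pattern
(`simulate_corpus` → `make_samples` → `train_regressor` → `predict_trace`);
see the methods vignette (`vignettes/petmoco-methods.Rmd`) for the models,
defaults and their rationale.

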