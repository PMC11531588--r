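# asariscan

Estimating the presence, count, and spatial distribution of buried asari
clams (*Ruditapes philippinarum*) from 3D acoustic-coring volumes.

## The problem

Clam stock surveys normally dig and sieve. An acoustic coring system
instead raster-scans a focused ultrasonic probe over the sediment (2 mm
pitch) and, after envelope processing, yields a non-negative 3D
reflection-intensity volume per experimental bucket — nominally
125 × 100 scan positions × 693 depth samples. Buried clams appear as
localized backscatter blobs between the sediment-surface reflection and
its *multiple* (the surface echo re-reflected once). `asariscan` turns
such volumes into voxel-level classifications and bucket-level clam
counts, for researchers developing non-destructive benthic survey
methods.

The analysis chain:

1. **Reflection windowing** — the depth profile
   `P(z) = Σₓᵧ I(x, y, z)` has its two most prominent peaks at the
   surface reflection and the multiple; the analysis window is the depth
   band between them.
2. **Depth standardization** — each bucket's window is linearly resampled
   to a common 693-sample grid.
3. **Local voxels** — overlapping 25 × 25 (px) × full-depth windows,
   stepping 1 px. A clam at position *p* is attributed to a window with
   footprint *R* iff `dist(p, R) < 11 px` (Euclidean point-to-rectangle,
   strict), so backscatter straddling a boundary is still credited.
4. **Two 3D-CNN classifiers** — presence/absence (2-class) and count
   (3-class: 0, 1, "2 or more"; counts ≥ 3 collapse to "2 or more"),
   trained with Adam on balanced label strata under **stratified group
   5-fold cross-validation** with buckets as groups (60/20/20
   train/val/test at fold granularity), early stopping on validation
   loss.
5. **Evaluation** — accuracy, F1 `= 2·p·r/(p+r)`, and ROC-AUC (midrank
   Mann–Whitney; macro-averaged one-vs-rest for the count task), pooled
   over the folds' held-out predictions.
6. **Count integration** — each bucket's 20 non-overlapping 25 × 25
   tiles are classified and summed (0 → 0, 1 → 1, "2 or more" → 2) into
   a bucket count; compared to truth by MAE, MRE (clam-bearing bucket
   types only — relative error is undefined at zero), and Pearson
   correlation.
7. **Grad-CAM** — rectified gradient-weighted feature-map sums,
   trilinearly upsampled and depth-averaged every 10 samples into
   panels, localize the evidence behind a prediction.

Because the measured volumes are large external deposits, the package
ships a physics-inspired simulator (`simulate_bucket()`) reproducing the
four experimental bucket types — `C` sand only, `A` 40 clams, `M`
mussels, `AM` clams + mussels — with surface/multiple bands, ellipsoidal
target blobs, 100 dB/m depth attenuation, and clipped Gaussian noise, so
every stage is testable end to end. The 3D convolutional networks
(im2col convolutions on BLAS, leaky rectifiers, global mean+max pooling,
Adam, early stopping) are implemented in the package itself, with
backpropagation verified against numerical differentiation in the test
suite.

## Worked example

```r
library(asariscan)

# one simulated clam bucket and its ground truth
cfg <- simulation_config("A", seed = 3)           # 125 x 100 x 693, 40 clams
sim <- simulate_bucket(cfg, bucket_id = "A1")
sim$volume
#> <acoustic_volume A1 (type A, simulated)> 125 x 100 x 693, max 77.9

# locate the inter-reflection window
win <- detect_analysis_window(depth_profile(sim$volume))
c(win$surface_z, win$multiple_z, win$z_start, win$z_end)
#> [1] 100 600 120 580

# label the 7,676 overlapping local voxels from the position table
man <- build_voxel_manifest(list(A1 = sim$volume), sim$truth)
table(man$count_label)
#>
#>  ge2
#> 7676
```

At 40 clams per scanned area, every 25 × 25 window — expanded by the
11 px attribution margin to an effective 47 × 47 footprint — captures
two or more clams in this bucket; the `0` and `1` strata of the count
dataset come from the C/M buckets and from sparser corners of other
clam buckets. This density is also why a well-classified non-overlapping
tiling integrates back to ≈ 2 × 20 = 40.

The full experiment — 20 buckets (5 per type), both classifiers,
grouped 5-fold CV, count integration, Grad-CAM — is one call:

```r
res <- run_experiment(run_config(seed = 1, out_dir = "runs/demo"))
str(res$summary)
```

On one CPU this takes roughly 10–13 minutes and printed, for seed 1:

```
$ presence_roc_auc            : num 0.927
$ presence_accuracy           : num 0.912
$ presence_f1                 : num 0.905
$ count_macro_roc_auc         : num 0.767
$ count_accuracy              : num 0.619
$ bucket_mre_by_type          : A 0.11, AM 0.10
$ count_correlation_overall   : num 0.952
```

Reading: held-out presence detection is near-ceiling on clean synthetic
volumes (ROC-AUC 0.93); the 3-class count task is harder (accuracy 0.62,
chance ⅓), as overlapping blobs blur the 1 vs "2 or more" boundary; yet
integrated bucket counts land within ~10 % of the true 40 clams for the
clam-bearing types, and estimated counts track true counts strongly
across all 20 buckets (r = 0.95). The A+AM-only correlation is reported
`NA` on synthetic panels: every clam-bearing bucket holds exactly 40
clams, so the truth has no variance there. Artifacts — ground truth,
bucket estimates, training curves, class-map and Grad-CAM figures — are
written under `out_dir`.

## Package tour

| Area | Functions |
| --- | --- |
| Simulation | `simulation_config()`, `simulate_bucket()`, `simulate_panel()`, `write_ground_truth()` |
| Volumes & preprocessing | `read_volume()`, `write_volume()`, `read_volume_raw()`, `depth_profile()`, `detect_analysis_window()`, `standardize_volume()`, `downsample_z()`, `normalize_volume()`, `preprocess_volume()` |
| Voxels & labels | `enumerate_windows()`, `assign_labels()`, `collapse_count()`, `build_voxel_manifest()`, `build_balanced_dataset()`, `extract_voxel()` |
| Models | `model_spec()`, `build_model()`, `train_config()`, `train_cnn()`, `predict_cnn()`, `cnn_dataset()` |
| CV & metrics | `make_fold_plan()`, `fold_roles()`, `evaluate_fold()`, `aggregate_folds()`, `f1_score()`, `roc_auc()`, `macro_roc_auc()`, `evaluate_predictions()`, `intensity_baseline_scores()` |
| Counts | `integrate_counts()`, `bucket_estimates()`, `distribution_metrics()`, `mae()`, `mre()`, `count_correlation()`, `render_distribution_map()` |
| Interpretation | `grad_cam()`, `z_average_panels()`, `render_explanation()` |
| Pipeline | `run_config()`, `run_experiment()`, `config_hash()` |

The methods vignette
(`vignettes/acoustic-coring-clam-estimation.Rmd`) documents the forward
model, the network design choices, the cross-validation scheme, numerical
conventions, and known limitations.
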