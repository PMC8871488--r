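# ceusperf

Perfusion-curve quantification and voxel-wise lesion classification for
contrast-enhanced ultrasound (CEUS).

CEUS images the transit of a microbubble bolus through tissue; malignant
breast lesions enhance faster and more strongly than benign ones. Given a
grayscale cine loop (`T × H × W` frames with timestamps) and an expert
lesion mask, `ceusperf`:

1. **pre-processes** the loop — Rec. 601 luminance conversion, rectangle
   cropping, 1-s temporal subsampling, rigid translation registration;
2. **fits a bolus model to every lesion voxel's time–intensity curve** by
   Levenberg–Marquardt least squares — either the exponentially modified
   Gaussian

   F(t) = (a·c·√(2π) / 2d) · exp((b−t)/d + c²/2d²) · [sgn(d) − erf((b−t)/(√2c) + c/(√2d))]

   or the gamma variate G(t) = A·tᵃ·exp(−t/b), with goodness of fit judged
   by the adjusted R², R̄² = 1 − (1−R²)(N−1)/(N−p−1);
3. **derives semi-quantitative markers** from each fit — wash-in and
   wash-out (extrema of the analytic first derivative), time to peak (TTP),
   time to maximal slope (TMSP), area under the enhancement curve (AUC),
   and the mean slope of increase computed on the measured curve,
   MSI = (1/N)·Σ[Cₜ(tᵢ₊₁) − Cₜ(tᵢ)] from the baseline end to TTP;
4. **assembles parametric maps** with explicit missing-data handling:
   voxels whose fit failed (no enhancement, non-convergence, peak outside
   the acquisition window, negative R̄²) stay colorless, never imputed;
5. **classifies voxels as benign or malignant** from 10 features per voxel
   (six markers + mean, median, max, SD of the measured curve), selected by
   minimum-redundancy maximum-relevance mutual information (mRMR, k = 6)
   and evaluated with seven classifiers (QDA, Gaussian naive Bayes,
   AdaBoost, random forest, kNN k = 3, logistic regression, RBF SVM) under
   **patient-grouped, class-stratified 10-fold cross-validation** — every
   voxel of a patient stays on one side of each split, so no patient leaks
   between training and test. Metrics: sensitivity, specificity,
   G_mean = √(sensitivity·specificity), and rank-based AUROC.

A synthetic cohort generator with known ground-truth kinetics
(`generate_cohort()`) makes the entire pipeline testable end to end without
clinical data.

## Worked example

```r
library(ceusperf)
set.seed(42)

## one voxel: simulate, fit, quantify --------------------------------------
tt <- seq(0, 89, by = 1)                       # 90 frames at 1 s
truth <- truth_params("EMG", c(150, 25, 5, 10), baseline_level = 15)
curve <- generate_voxel_curve(truth, tt, noise_sd = 5)
fit <- fit_curve(curve, "EMG")
fit
#> <ceus_fit> EMG converged, adj R^2 = 0.9649, params = (153.92, 25.034, 4.454, 9.7193)

markers <- compute_markers(fit, window = c(0, 89))
markers$msi <- compute_msi(detect_baseline_end(curve), markers$ttp)
markers
#> <marker_set>
#>   wash_in  9.94326
#>   wash_out -5.68725
#>   ttp      29.76
#>   tmsp     23.69
#>   auc      1715.82
#>   msi      7.62528
```

The fit recovers the generating parameters (150, 25, 5, 10) to a few
percent under noise; wash-in is the peak inflow rate (intensity/s), TTP
the time of maximal enhancement (s), AUC the integral of the fitted
enhancement (intensity·s), MSI the mean per-sample rise of the measured
curve up to the peak.

```r
## a cohort: features -> mRMR -> patient-grouped CV -------------------------
cohort <- generate_cohort(6, 0.5, "well_separated", seed = 1,
                          voxels_benign = 20, voxels_malignant = 40,
                          frame_shape = c(12, 12))
cohort
#> <synthetic_cohort> well_separated/EMG: 6 patients (3 malignant, 3 benign), 180 lesion voxels, seed 1

features <- cohort_features(cohort, "EMG")
selected <- mrmr_select(discretize_features(features), features$class_label, k = 6)
as.character(selected)
#> [1] "wash_in"  "ttp"      "wash_out" "auc"      "msi"      "tmsp"

labels <- setNames(vapply(cohort$patients, `[[`, "", "class_label"),
                   vapply(cohort$patients, `[[`, "", "patient_id"))
folds <- make_patient_folds(labels, n_folds = 3, seed = 1)
cv <- evaluate_classifiers(features, folds,
                           c("LogisticRegression", "QDA", "kNN"),
                           features = selected, seed = 1)
cv
#> <cv_result> mean ± SD over folds (%):
#>   LogisticRegression   sens 100.0 ±  0.0  spec 100.0 ±  0.0  G 100.0 ±  0.0  AUROC 100.0 ±  0.0
#>   QDA                  sens 100.0 ±  0.0  spec 100.0 ±  0.0  G 100.0 ±  0.0  AUROC 100.0 ±  0.0
#>   kNN                  sens 100.0 ±  0.0  spec 100.0 ±  0.0  G 100.0 ±  0.0  AUROC 100.0 ±  0.0
```

On the strongly separated synthetic scenario the classes are perfectly
distinguishable — real lesions overlap far more. Kinetics-driven markers
(wash-in, TTP, AUC) dominate the mRMR ranking, as they should when the
classes differ in enhancement speed and strength.

Maps and exports: `fit_roi()` + `assemble_map()` produce per-marker
`H × W` maps; `write_map()` exports a 32-bit float TIFF and an RGBA PNG
preview with failed voxels transparent; `write_cohort()`,
`write_curves_csv()`, `write_fits_json()` persist cohorts, curves and fit
tables. `scripts/classify.R` is a command-line wrapper over the feature
table → folds → classifiers path.

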