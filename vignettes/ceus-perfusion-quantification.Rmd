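---
title: "Quantifying CEUS perfusion curves and classifying lesion voxels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CEUS perfusion curves and classifying lesion voxels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceusperf)
```

## The problem

Contrast-enhanced ultrasound (CEUS) images the passage of a microbubble
bolus through tissue. In breast lesions, malignant neovascularity produces
faster and stronger enhancement than benign tissue, so the shape of each
voxel's time–intensity curve carries diagnostic information. `ceusperf`
turns a cine loop plus an expert lesion mask into per-voxel kinetic
markers, parametric maps, and a benign/malignant voxel classification
benchmark evaluated without patient leakage.

The pipeline is: pre-process the loop (luminance conversion, cropping,
1-s temporal subsampling, rigid translation registration), extract a
perfusion curve per masked voxel, fit a bolus model per voxel, derive
semi-quantitative markers, select features by mutual information, and
cross-validate a battery of classifiers with folds that partition
*patients*, not voxels.

## The two bolus models

The **exponentially modified Gaussian (EMG)** is the convolution of a
Gaussian bolus (center $b$ s, width $c$ s) with a one-sided exponential
dispersion kernel (decay time $d$ s), scaled so the peak approaches $a$
as $d \to 0$:

$$F(t) = \frac{a\,c\sqrt{2\pi}}{2d}
  \exp\!\Big(\frac{b-t}{d} + \frac{c^2}{2d^2}\Big)
  \Big[\operatorname{sgn}(d) - \operatorname{erf}\Big(\frac{b-t}{\sqrt2 c}
  + \frac{c}{\sqrt2 d}\Big)\Big],$$

with the standard normalized error function
$\operatorname{erf}(x)=\tfrac{2}{\sqrt\pi}\int_0^x e^{-u^2}du$. Several
printed variants of this formula circulate with the $1/\sqrt\pi$
normalization of erf dropped or the exponent grouped ambiguously; we fix
both choices by requiring that the expression equal the numeric
convolution of the Gaussian with the exponential kernel, which the test
suite verifies to a relative error below $10^{-6}$ (and which also forces
the Gaussian-limit peak height $F(b)\to a$). Evaluation is stabilized
through the scaled complementary error function
$\mathrm{erfcx}(x)=e^{x^2}\mathrm{erfc}(x)$, using the identity
$F(t) \propto e^{-(t-b)^2/(2c^2)}\,\mathrm{erfcx}(w)$: no intermediate
overflow occurs anywhere on the real line. The analytic derivative
reduces to $F'(t) = \big(a\,e^{-(t-b)^2/(2c^2)} - F(t)\big)/d$.

The **gamma variate (GVF)** is $G(t) = A\,t^a e^{-t/b}$ on $t \ge 0$,
with closed-form landmarks used as test oracles: peak at $t = ab$ of
height $A(ab)^a e^{-a}$, maximal slope at $t = b(a-\sqrt a)$, and total
area $A\,b^{a+1}\Gamma(a+1)$.

**Time origin.** A time shift of the EMG is *exactly* absorbed by its
location parameter $b$, so EMG fits use the absolute time axis and need
no explicit onset. The GVF starts at $G(0)=0$ and is not
shift-invariant, so it is evaluated on time since the detected baseline
end. This asymmetry is deliberate: it removes a redundant (and therefore
unidentifiable) onset parameter from the EMG fit.

**Parameter domain.** Fits are restricted to the physiological branch
($a, c, d > 0$ for EMG; $A, a, b > 0$ for GVF), so
$\operatorname{sgn}(d) = 1$ in practice; the sign factor is nevertheless
implemented so the expression stays faithful for $d<0$.

## Fitting

`fit_curve()` estimates parameters by Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`, the reference MINPACK implementation), after
subtracting the baseline level (mean of the samples up to the detected
baseline end). Choices that matter:

* **Baseline end** (`detect_baseline_end()`): the last sample before the
  first intensity exceeding `mean + k_sigma * SD` of the first `m`
  samples (`k_sigma = 3`, `m = 5`). No detection rule is standard for
  this quantity; a k-sigma rule on the pre-contrast segment is the
  simplest that degrades gracefully with noise. A curve that never
  crosses the threshold raises a *no-enhancement* condition, which
  `fit_curve()` converts into a non-converged record.
* **Initialization**: amplitude from the observed peak, location from
  the observed peak time, width $c_0$ = ¼ of the enhancement duration
  (time spent above 25 % of peak), decay $d_0$ from the 63 % post-peak
  decay time. Up to `n_restarts = 4` deterministic multiplicative
  jitters (0.5×, 2×, 0.25×, 4×) are tried when a start fails.
* **Acceptance of a solution**: converged LM status, finite parameters
  and residuals, *and* a fitted peak strictly inside the acquisition
  window. The last condition matters: flat-ish curves admit a degenerate
  ramp-like EMG optimum whose peak sits at the window edge; treating it
  as a restart trigger rather than a result removed essentially all
  spurious fits in validation (0 failures on 400 noiseless curves,
  maximum relative parameter error 0.4 %).
* **Tolerances**: `ftol = ptol = 1e-10`, `max_iter = 200`. These are far
  below the noise floor of any realistic acquisition; they are chosen so
  that noiseless round-trip tests are limited by the optimizer, not the
  tolerance.

Goodness of fit is the adjusted $R^2$,
$\bar R^2 = 1 - (1-R^2)(N-1)/(N-p-1)$ with $p = 4$ (EMG) or $3$ (GVF).
It requires $N > p + 1$ samples and non-constant observations, and it
*can* be negative for fits worse than the mean predictor — such voxels
are stored as computed but treated as failed when painting maps.

## Markers

`compute_markers()` evaluates the fitted model and its analytic
derivative on a dense grid (default `grid_dt = 0.01` s; time-valued
markers are accurate to one grid step): TTP is the grid argmax of the
model, wash-in/wash-out the extrema of the derivative, TMSP the argmax
of the derivative, and AUC the trapezoidal integral of the fitted
enhancement component (baseline excluded) over the window. A marker
whose extremum lands on the window boundary has no interior stationary
point and is flagged *undefined* rather than reported.

MSI (mean slope of increase) is the one marker computed on the
*measured* curve: the mean of consecutive intensity increments from the
baseline end to the sample nearest TTP, which telescopes exactly to
$[C_t(t_{TTP}) - C_t(t_0)]/N$. AUC and the other five markers are
computed on the fitted model — the fitted curve is the de-noised
estimate of the voxel's kinetics, whereas MSI's defining sum is written
in terms of the sampled curve; both conventions are therefore applied
where each is natural, and the choice is recorded here because raw-curve
AUC would differ slightly under noise.

## Parametric maps and failure handling

`fit_roi()` fits every masked voxel independently (the result is a pure
function of loop and mask; row order never depends on execution order)
and keeps failed fits in the table with a `reason`
(`no_enhancement`, `no_convergence`, `peak_outside_window`).
`assemble_map()` paints only voxels whose fit converged, whose
adjusted $R^2$ is non-negative, and whose marker is defined — everything
else stays invalid (`NA` values, transparent pixels in the PNG export),
never imputed. Counts are conserved exactly:
valid + failed + undefined = masked. `summarize_fit_quality()` reports
mean ± sample SD (denominator $n-1$) of adjusted $R^2$ over converged
voxels per model.

## Features and selection

Each usable voxel yields ten features: the six markers plus mean,
median, max and sample SD of the measured curve. Voxels with a failed
fit or any undefined marker raise a skip condition and are dropped with
a count — mirroring how GVF fails to quantify a non-negligible fraction
of noisy voxels in practice.

mRMR selection works on 3-bin z-score codes (below −1, within ±1, above
+1 — a standard coarse discretization for mutual-information estimation;
finer binning mainly adds estimation variance at these sample sizes).
The greedy criterion is the mutual-information difference (MID): pick
$\arg\max_f I(f;y)$, then repeatedly
$\arg\max_f I(f;y) - \tfrac1{|S|}\sum_{s\in S} I(f;s)$, ties broken by
column order. `k = 6` by default, matching the size of the reported
marker panels in this literature. One behavior worth knowing: when one
feature separates the classes almost perfectly, every other feature's
class information is subsumed by it ($I(f; f_1) \approx I(f;y)$), all
subsequent objectives collapse toward zero, and the tail of the ranking
becomes essentially arbitrary. This is a property of MID itself, not of
the implementation; the quotient scheme (MIQ) is no more stable in this
regime. Consequently only the *head* of the ranking should be
interpreted on strongly separated data.

## Classification benchmark

`make_patient_folds()` shuffles patients deterministically by seed and
deals them round-robin within class (continuing across classes so no
fold stays empty): folds partition patients, every voxel of a patient
stays on one side of each split, and per-class fold sizes differ by at
most one. `evaluate_classifiers()` z-scores features with training-fold
statistics only, trains each classifier, and scores held-out voxels.
Malignant is the positive class; hard labels use the 0.5 probability
threshold; AUROC uses the Mann–Whitney rank formulation with half
credit for ties. Reported dispersions are over-fold sample SDs. Folds
with a single-class test set are skipped with a message rather than
zero-filled.

The battery: QDA (`MASS::qda`), Gaussian naive Bayes and RBF-kernel SVM
(`e1071`), random forest (`randomForest`, 200 trees, seeded per fold),
kNN with $k = 3$ (`class::knn`), logistic regression (`stats::glm`),
and a discrete AdaBoost.M1 over depth-1 `rpart` stumps (50 rounds)
implemented here because no AdaBoost package is available — it is
deterministic and uses the usual $\alpha_m = \tfrac12\log\frac{1-\varepsilon_m}{\varepsilon_m}$
reweighting with a logistic transform of the additive margin as score.
SVM ranking scores are raw decision values rather than Platt-scaled
probabilities, avoiding the internal cross-validation randomness of
probability calibration. No hyperparameter tuning is performed anywhere;
all other settings are the libraries' defaults.

## What the synthetic generator does and does not emulate

`generate_cohort()` builds patients with a circular lesion in a
24 × 24 frame over a 90-frame, 1-s-resolution loop (a realistic
post-subsampling CEUS acquisition), intensities in nominal 0–255
arbitrary units with a flat baseline of 15. Kinetic parameters are drawn
per patient from class-conditional distributions (malignant: stronger
amplitude, shorter time to peak; benign: weaker, slower — see
`scenario_config()` for the frozen constants) with a 5 % lognormal
per-voxel jitter on top; malignant lesions are three times larger (150
vs 50 voxels), giving the ~3:1 malignant:benign voxel imbalance typical
of such cohorts at a 0.56 malignant patient fraction. Noise is additive
zero-mean Gaussian clipped at zero (SD 4 in the default scenario, 10 in
`overlapping`, 20 in `noisy`); the GVF arrival time is drawn per patient
uniformly on 5–10 s and snapped to the frame grid.

It deliberately does **not** simulate speckle (multiplicative noise), RF
beamforming, B-mode texture, attenuation, or patient motion beyond
optional global frame shifts for testing registration. Passing tests on
these cohorts therefore demonstrate correctness of the estimation and
evaluation machinery under known kinetics — not clinical performance.
The `well_separated` scenario is constructed so that classes are
separable (cross-validated AUROC ≈ 100) and the permutation null sits at
50; real lesions overlap far more, which is why the published
voxel-level AUROC figures in this literature are nearer 90 than 100.

## Problem sizes and runtime choices

The test suite fits hundreds of single curves (200 noiseless recovery
curves per model; 100 curves per noise level of the SD sweep
{0, 5, 10, 20}) and one 20-patient, 2 000-voxel end-to-end study; at
roughly 10 ms per voxel fit the whole suite runs in a few minutes on one
core. `scripts/acceptance.R` regenerates the 20-patient cohort from its
`--seed`, fits both models on all voxels, and reruns the
selection + cross-validation pipeline (~40 s). Cohort-scale marker grids
use `grid_dt = 0.05` s (markers accurate to 0.05 s, ample for 1-s
sampled curves); single-curve analyses default to 0.01 s. The
permutation null reported by the script is the mean over five
voxel-label permutations — a stable estimate whose expectation is
exactly the single-permutation value.

## Coordinates and conventions

All indices are 1-based R conventions: `(row, col)` voxel coordinates,
rectangles `(row0, col0, height, width)` with an inclusive 1-based
corner, and `t0_index` the index of the last baseline sample.
Frame stacks are `T × H × W` arrays; masks are `H × W` logical matrices.

## Known limitations

* Registration is integer-pixel rigid translation (FFT
  cross-correlation); subpixel or non-rigid motion is out of scope,
  though `register_translation()` accepts a pluggable estimator.
* The adjusted-$R^2$ summary pools voxels across patients; per-patient
  averaging would weight patients equally instead.
* Discrete mutual information on 3-bin codes is biased upward at small
  sample sizes; rankings are meaningful, absolute MI values less so.
* DICOM video demuxing and vendor region tags are not parsed; region
  rectangles and timestamps are explicit inputs.
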