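---
title: "Predicting prostate CTV shifts from sagittal anatomical features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting prostate CTV shifts from sagittal anatomical features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctvshift)
```

## The problem

In image-guided prostate radiotherapy the clinical target volume (CTV —
prostate plus seminal vesicles) moves between the planning CT and each
daily pretreatment cone-beam CT (CBCT), driven mainly by rectal and
bladder filling. After automated rigid registration on the pelvic bones,
the residual target displacement (the *CTV shift*, in mm along the
left–right, superior–inferior and anterior–posterior axes, positive =
left/superior/anterior) is usually corrected by a subjective manual
matching step. `ctvshift` implements a semi-automated alternative: a few
geometric measurements of the bladder, rectum and prostate on the
isocenter sagittal plane, taken relative to two fixed pubic-bone
landmarks, are fed to regression models that predict the SI and AP shift
components directly (LR motion is clinically negligible and carried only
as bookkeeping).

## Features

Two landmarks anchor every measurement on the (bone-registered) sagittal
plane: **S**, the superior–posterior edge of the pubic bone, and **I**,
its inferior–posterior edge. `locate_feature_points()` selects them as
the bone vertices maximizing $s - a$ and $-s - a$ respectively, with ties
resolved toward the more superior/inferior and then more posterior
vertex. Seven distances are measured per image:

| distance | definition |
|---|---|
| d1 | S to the most-posterior bladder point (ties: most superior), Euclidean |
| d2 | S to the superior bladder wall along the SI line through S |
| d3 | S to the rectal anterior wall along the AP line through S |
| d4 | rectal diameter on that same AP line |
| d5, d6 | as d3, d4 on the AP line through I |
| d7 | d6 − d4 |

The nine features of a planning/pretreatment image pair are
$f_l = d_l^{\mathrm{CBCT}} - d_l^{\mathrm{pCT}}$ for $l = 1..7$, plus the
prostate-center displacement along SI ($f_8$) and AP ($f_9$), where the
prostate center is the midpoint of the axis-aligned extents (the
one-click "middle point", not the area centroid). Feature 3 measures the
anterior displacement of the upper rectal wall; rectal filling pushes the
target anterior–superiorly, so $f_3$ correlates *negatively* with both
shift components.

Numerical conventions worth stating:

* Distances are positive magnitudes in their drawn directions; a wall on
  the wrong side of its landmark raises a "not measurable" error rather
  than returning a negative value or a silent `NaN`.
* With more than two rectal crossings (non-convex lumen) the outermost
  pair defines the anterior wall and the diameter — wall and diameter are
  outer-boundary notions.
* Whether d1 should be a Euclidean or an AP-projected distance is
  ambiguous in the clinical description; the package uses the Euclidean
  reading (the measured point is configurable in principle because only
  `measure_distances()` touches it).
* $f_7 \equiv f_6 - f_4$ makes the feature matrix rank-deficient by
  construction. This is intentional and documented, not "fixed": the
  regressors never invert the feature Gram matrix.
* All features are differences of bone-relative measurements, so a rigid
  translation of an entire anatomy changes nothing (tested to $10^{-9}$
  mm).

## The synthetic cohort generator

No patient images ship with the package; `simulate_cohort()` replaces
them. Each patient receives a randomized baseline anatomy (smooth convex
superellipse contours for bladder, rectum — a high-exponent rounded tube —
prostate and CTV, and a convex quadrilateral pubic bone, with per-patient
jitter of centers and semi-axes). Each fraction then draws three latent
unit-variance filling states — $u$ (upper rectum), $v$ (lower rectum),
$w$ (bladder) — and produces a pretreatment anatomy:

* the rectal anterior wall moves anteriorly by $3u$ mm (upper) and $3v$
  mm (lower), the posterior wall following at 60% of that displacement
  (filling both displaces and distends the lumen);
* the bladder is scaled by $1 + 0.05\,w$;
* the prostate and CTV are rigidly translated by the ground-truth shift
  $\mathrm{si} = 1.05u + 0.30w + \varepsilon_{si}$,
  $\mathrm{ap} = 1.45u + 0.35v + 0.35w + \varepsilon_{ap}$, with noise
  SDs 0.30 and 0.45 mm, and $\mathrm{lr} = \varepsilon_{lr}$ with SD
  0.12 mm.

The coupling constants were fixed once, from the clinically reported
scales: pooled cohorts give mean |SI| ≈ 0.9 mm, mean |AP| ≈ 1.3 mm and
mean |LR| < 0.1 mm, and the target moves along the anterior–superior /
posterior–inferior diagonal that pelvic organ filling produces. The
recorded `reference_shift` equals the applied CTV translation exactly
(generator bookkeeping), so centroid differences recover it to machine
precision.

Manual measurement is emulated by click noise: every clicked wall/bone
point adds N(0, 0.5 mm) to its distance (diameters involve two clicks,
hence SD $0.5\sqrt{2}$), and the prostate-center clicks use a larger SD
of 1.5 mm per axis because the prostate boundary is poorly visible on
CBCT. The larger COP noise matters structurally: in a rigid-translation
generator features 8/9 equal the true shift plus click noise, so with
bone-sharp COP clicks they would trivially dominate the ranking, unlike
clinical data where consensus reference shifts also weigh the seminal
vesicles. With these defaults, feature 3 is the strongest correlate of
both components in effectively every seeded cohort.

What the generator deliberately does **not** emulate: CTV rotation and
deformation (translation only), 3D anatomy, intrafraction motion,
realistic HU calibration, and organ-boundary ambiguity. Passing tests
therefore demonstrate internal consistency of the method chain at
clinical shift scales — not clinical accuracy on real CBCT, where
residuals are dominated by exactly the effects excluded here. The
synthetic noise floor is also cleaner than clinical teacher data, which
is why cross-validated residuals on default cohorts (≈ 0.5 mm) sit below
the ≈ 1 mm reported for patient data.

## Regressors

Five architectures, each fitted separately per direction (SI, AP), all
behind `train_regressor()` / `predict()`:

* **LM-ANN** — single hidden layer (tanh, linear output) trained by
  full-batch Levenberg–Marquardt on the SSE; the damping parameter starts
  at $\mu_0 = 0.001$ and is divided/multiplied by 10 on
  accepted/rejected steps.
* **BR-ANN** — Bayesian regularization inside the same LM loop
  ($\mu_0 = 0.005$): minimizes $\beta\,\mathrm{SSE} + \alpha\|w\|^2$ with
  $\alpha, \beta$ re-estimated each accepted epoch from MacKay's
  effective-number-of-parameters update.
* **SCG-ANN** — Møller's scaled conjugate gradient with initial scale
  $\lambda = 5\times10^{-7}$.
* **SVR** — $\varepsilon$-insensitive support vector regression (libsvm
  via `e1071`), RBF kernel with $\gamma = 1/p$ on z-scored inputs, cost
  $C = \mathrm{IQR}(y)/1.349$ computed from the training targets (a
  robust scale estimate; zero IQR falls back to $C = 1$ with a warning).
* **RF** — regression forest (`randomForest`), bootstrap per tree,
  $\mathrm{mtry} = \lceil p/3 \rceil$, minimum 5 observations per leaf.

Design choices where the method description was open: one hidden layer
with tanh/linear activations; inputs and targets z-scored on the training
fold (standard for ANN/SVR; RF is scale-free and left raw); epoch cap
1000 with gradient tolerance $10^{-7}$ and no early-stopping split (BR
supplies the regularization); SVR dual tolerance $10^{-6}$. Tuning grids
follow the clinical protocol: hidden nodes 4–10, $\varepsilon \in
\{0.01, 0.05, 0.1, 0.3, 0.5, 1.0\}$, trees $\in \{10, 30, 50, 70, 100,
150\}$; `select_hyperparameters()` picks the grid value with the smallest
mean absolute *training* error, ties toward the smaller value.

Determinism: ANN initialization and RF bootstraps are seeded, and refits
with the same seed are bit-reproducible. Full-batch LM is
order-independent in exact arithmetic but its accept/reject path can
amplify floating-point summation reordering; SVR (SMO working-set order)
and RF (bootstrap indexing) are intrinsically data-order dependent. The
shuffle-invariance test therefore uses a convergent noiseless fit for the
ANN and fixed-seed determinism for the others.

## Evaluation protocol

`rank_features()` orders features by the mean of |Spearman ρ| with the SI
and AP shifts (ties toward the lower index) and exposes the nested
subsets used in the feature-count search. `run_lcv()` implements
leave-one-*patient*-out cross-validation: all fractions of one patient
are held out together, and — by default — the feature ranking is
recomputed inside each training fold so no information from the held-out
patient leaks into the subset choice (`rank_per_fold = FALSE` gives the
pooled variant, since the clinical protocol is ambiguous on this point).
`run_validation()` fits on a full training cohort and predicts a disjoint
validation cohort. Residuals are absolute differences per direction;
summaries report mean ± sample SD (n − 1; configurable to population SD)
and the maximum, per direction and pooled.

Comparison statistics:

* `spearman_rho()` — average-rank ρ with an exact permutation p-value for
  n ≤ 9 and the t approximation otherwise.
* `steel_dwass()` — all-pairs rank comparisons referred to the
  studentized range with tie-corrected variances (large-sample
  approximation); an exact enumeration path exists for two small groups
  and is used as an independent check in the tests. Null simulations put
  the family-wise type-I error at α = 0.05 inside [0.03, 0.07].
* `f_test_variance()` — two-sided variance-ratio F test.
* `cohens_kappa()` — continuous shifts are discretized to 1 mm bins
  centered on integer millimeters (the clinical discretization is
  unstated; the bin width is exposed).
* `dice_coefficient()` — polygon-clipping overlap; requires at least one
  convex contour (all generated organs are convex superellipses).

## The intensity-matching comparator

`grey_value_match()` emulates the clinical soft-tissue fallback: an
exhaustive integer-pixel translation search (default ±15 mm) maximizing
the correlation ratio of the two images inside the CTV + 5 mm ROI,
followed by three-point parabolic sub-pixel refinement per axis (skipped
when the integer optimum is already perfect, and ties resolved toward the
smallest translation). `rasterize()` produces the images: constant organ
intensities over a soft-tissue background at 1 mm pixels with optional
Gaussian intensity noise, and an optional rectal gas pocket painted at
air intensity. Gas changes *only* pixel intensities — contours, and hence
geometric features, are untouched. This reproduces the qualitative
clinical finding the comparator exists for: inserting a gas pocket in the
pretreatment image degrades the intensity match substantially (from
≈ 0.2–0.3 mm to several mm in the packaged experiments) while the
f3-driven regressors are unaffected, because the feature measures the
wall, not the lumen intensity.

## Problem sizes and reproducibility

The packaged experiments use the clinical cohort geometry — 10 training
patients × 38 fractions (380), and 10 validation patients × 10 fractions
(100) — with 20–50 reseeded replicates for ranking-stability and
gas-comparator statements and 2000 replicates for the null calibration of
the statistical tests; these sizes give stable Monte-Carlo estimates at
interactive run times. All randomness flows from explicit seeds through
named substreams (generator, click noise, trainer initialization,
bootstrap), every artifact written by `run_pipeline()` embeds its seed
and a config hash, and rerunning any stage with the same configuration
reproduces its outputs bit-identically.

## Known limitations

* 2D sagittal geometry only; no DICOM/DICOM-RT interfaces.
* Rigid CTV translation: rotation/deformation — the dominant failure mode
  on real anatomy — is out of scope by design.
* The generator's organ-variation distributions are modelling choices,
  not fitted to images; only their first/second-order shift statistics
  and the feature-ranking structure are calibrated to reported clinical
  values.
* `dice_coefficient()` needs one convex polygon; arbitrary non-convex
  pairs are rejected rather than approximated.
* The Steel–Dwass p-values use the asymptotic studentized-range
  reference; for very small groups prefer the exact two-group path.
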