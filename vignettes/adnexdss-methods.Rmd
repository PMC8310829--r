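---
title: "Methods: segmentation-robust ultrasound radiomics and rule-based risk integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation-robust ultrasound radiomics and rule-based risk integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`adnexdss` implements a decision support system (DSS) that assigns an
ovarian mass seen on transvaginal ultrasound to a *very low* or
*medium–high* risk of malignancy. This vignette is the package's own
account of the method: the model and its assumptions, the parameters that
matter, what the synthetic phantoms do and do not emulate, and the design
choices made where the design was genuinely open.

## 1. The pipeline

For one mass the system consumes a single 2D grayscale frame (DICOM or
PNG), a manual closed-contour segmentation, the echotexture class assigned
by the examiner (solid / cystic / mixed), an acoustic-shadow flag, the
serum CA-125 level (U/mL) and the menopausal status. Processing proceeds:

1. **Contour manipulation** (`perturb_contour()`): random smooth variants of
   the manual contour emulate segmentation by different operators.
2. **Feature extraction** (`extract_case_features()`): IBSI-style 2D
   morphometry and texture per contour variant.
3. **Stability selection** (`feature_stability()`, `select_panel()`):
   features unstable across variants are discarded per echotexture class.
4. **Risk classification** (`train_ensemble()`, `predict_radiomic()`): one
   linear model per echotexture class scores the per-case median feature
   vector.
5. **Rule integration** (`integrate_risk()`): acoustic shadow and
   menopause-corrected CA-125 override or confirm the radiomic prediction.
6. **Evaluation** (`dss_metrics()`): diagnostic accuracy against histology
   with exact binomial confidence intervals.

## 2. Contour manipulation

The manual segmentation is the dominant operator-dependent input, so the
radiomic stage is built to be robust to it. Each variant displaces the
contour radially about its centroid by a random field
$f(\theta) = \sum_{h=1}^{H} a_h \cos h\theta + b_h \sin h\theta$, with
$a_h, b_h \sim N(0,1)$, rescaled so the peak displacement is at most
`amplitude_frac` times the equivalent radius $r_{eq}=\sqrt{A/\pi}$ (a
per-variant utilization factor in (0.5, 1] varies the magnitude). Defaults:
`n_variants = 20`, `amplitude_frac = 0.05`, `H = smoothness = 6`.

*Why these values.* Careful re-tracings of the same mass by different
operators differ by a few percent of the radius, concentrated in smooth,
low-frequency disagreement rather than per-vertex jitter; harmonics up to
order six give exactly that. At the defaults every variant keeps a Jaccard
overlap of at least 0.85 with the original mask, and the equivalent radius
changes by no more than `amplitude_frac` — both enforced by tests. Radial
parameterization (rather than independent vertex jitter) guarantees the
output stays one simple closed curve for the star-shaped contours this
domain produces. Variants that would leave the frame are clipped to its
bounds with a warning. Affine jitter (translation/scale) is deliberately
not added: it is not what inter-operator tracing disagreement looks like,
and it would leak mass size into the stability statistic.

## 3. Radiomic features

All texture families run on discretized grey levels
$\ell = 1 + \lfloor n_{bins}(I - I_{min})/(I_{max} - I_{min})\rfloor$,
clamped to $n_{bins}$ at the maximum; a constant region-of-interest maps to
level 1. Default: fixed bin *number* 64 over the ROI's own min–max — the
common IBSI-compliant choice for modality-unitless intensities, and it
makes texture features invariant to affine intensity rescaling (tested).

* **First order** (13 features): mean, variance, skewness, kurtosis,
  energy, histogram entropy/uniformity, percentiles (10/90), IQR, range,
  mean absolute deviation, RMS.
* **Shape** (9): pixel-count area (mm²), marching-squares perimeter (the
  padded mask is lightly Gaussian-smoothed, σ = 0.9 px, before the
  0.5-isoline so a digital disk's perimeter lands within ~0.5% of 2πr
  instead of the ~5% staircase overestimate), equivalent diameter, ellipse
  major/minor axes from second moments, eccentricity, circularity
  $4\pi A/P^2$, convex-hull solidity, maximum Feret diameter.
* **GLCM** (8 features × distances {1, 2, 4}): symmetric co-occurrence
  matrices over within-mask pairs along the four 2D directions,
  features averaged over directions ("averaged" aggregation): contrast,
  dissimilarity, inverse difference, angular second moment, correlation,
  joint entropy, cluster shade, cluster prominence. A constant ROI is the
  documented degenerate case (contrast 0, ASM 1, correlation defined as 1).
* **GLRLM** (7): run-length matrices along the four directions, averaged:
  SRE, LRE, grey-level and run-length non-uniformity, run percentage,
  low/high grey-level run emphasis. Runs break at the mask boundary.
* **GLSZM** (5): 8-connected equal-level zones: small/large zone emphasis,
  zone-size and grey-level non-uniformity, zone percentage.

The candidate catalogue is identical across echotexture classes; panels
diverge only after stability selection. For **mixed** masses the intensity
and texture families are additionally computed on the solid subregion —
pixels above the Otsu threshold within the contour, largest connected
component — and name-spaced `solidsub_`. Otsu was chosen because it is
deterministic and parameter-free; when the subregion degenerates (< 10 px)
the whole-mask values are substituted so the catalogue stays complete and
finite. Every feature equals a brute-force pair/run/zone enumeration oracle
to 10⁻¹⁰ on random ROIs, and angle-averaged features are invariant to 90°
rotation to 10⁻⁸ (property tests).

## 4. Stability selection

With masses as subjects and contour variants as raters, the one-way
intraclass correlation
$ICC(1,1) = (MS_b - MS_w)/(MS_b + (k-1)MS_w)$, clipped to $[0,1]$, scores
each feature; features with zero total variance are flagged degenerate and
excluded. Unequal variant counts fall back to the harmonic-mean $k$ with a
warning. Selection keeps features with ICC ≥ 0.75 — the conventional
radiomics robustness cut-off — ordered by descending ICC with the feature
name as a deterministic tie-break. Panels are learned per echotexture class
on training data only and frozen into the model file. Stability is assessed
pooled across the training masses of a class (not per image): the per-image
alternative estimates $MS_b$ from one subject and is essentially noise at
clinical cohort sizes.

## 5. The classifier ensemble and its operating point

Per echotexture class: z-score standardization (fit on training folds
only), then a linear SVM (cost 1; a logistic alternative is selectable).
Stratified 10-fold cross-validation (folds reduced automatically when a
class has fewer cases) yields pooled out-of-fold scores; the operating
threshold is the score cut maximizing sensitivity subject to out-of-fold
specificity ≥ `specificity_floor` (default **0.90**), falling back to the
Youden optimum if the floor is unreachable. The final model is refit on all
training cases. At inference, per-variant features are aggregated by the
**median** across contour manipulations before scoring — a robust location
estimate that makes the prediction insensitive to any single tracing, which
is the point of the manipulation step.

Why a specificity-first operating point: the CA-125 override downstream
converts high biomarker levels into medium–high calls regardless of the
image, which buys sensitivity at some specificity cost; running the
radiomic stage specificity-first balances the integrated system. A linear
model is deliberate: tens-to-hundreds of training cases per stratum with
~60–110 candidate features is exactly the regime where linear SVMs on
standardized features are the robust default.

Models serialize to a versioned JSON archive (panels, scaler parameters,
weight vector, intercept, threshold, config, seed) — a linear model is just
$(w, b)$, so the archive is plain text and round-trips to identical
predictions.

## 6. Decision rules

CA-125 thresholds are 71 U/mL (postmenopausal; twice the upper normal
level) and 200 U/mL (premenopausal), compared **strictly** (`> t`): the
clinical phrasing "higher than" reads as strict, the convention is
documented, configurable, and boundary cases are tested. Precedence:
CA-125 above ⇒ medium–high (with or without shadow); otherwise shadow ⇒
very low; otherwise the radiomic class stands. The radiomic prediction is
still computed and logged on override routes for audit but cannot change
the final class. `integrate_risk()` is a pure function; its 8-row truth
table and the monotonicity of the final class in CA-125 are asserted
exhaustively.

## 7. Evaluation

The 2×2 table against histology (medium–high ↔ malignant is the positive
pairing) yields sensitivity, specificity, accuracy, PPV and NPV, each as
numerator/denominator, a percentage rounded half-up to one decimal, and an
exact Clopper–Pearson 95% CI from beta quantiles
(`qbeta(α/2, x, n−x+1)`, `qbeta(1−α/2, x+1, n−x)`; closed forms at the
boundaries). Only the exact method reproduces the worked-example bounds
the package tests against (e.g. 83.2% lower bound for 20/20 and
51.9–95.7% for 12/15); a metric with a zero denominator is returned as
undefined without blocking the others. The exact interval is conservative:
its empirical coverage at p = 0.8, n = 30 exceeds 95% (tested by
simulation). Area-under-curve estimation is out of scope — the package
evaluates the binary operating point the rules produce.

## 8. The phantom simulator

`generate_phantom()` builds frames with the statistical structure the DSS
assumes, so every downstream stage is testable with known ground truth:

* background: smooth tissue-intensity field (Gaussian-blurred noise,
  mean 0.5, sd 0.06 of dynamic range) times unit-mean Rayleigh speckle,
  lightly blurred (σ = 1 px), with local contrast `1 + τ(S − 1)`;
* the mass: an ellipse (equivalent radius 18–28 px at 0.3 mm/px — masses
  of roughly 1–1.7 cm, TUS-typical — aspect 0.65–1) with low-order
  harmonic boundary noise; cystic interiors are hypoechoic (gain 0.16),
  solid interiors hyperechoic and textured (gain 1.35), mixed masses are
  cystic with 1–2 solid mural nodules;
* malignancy raises the boundary-irregularity amplitude (0.03 → 0.12 of
  $r_{eq}$) and the texture-contrast parameter τ (0.5 → 1.1 in echogenic
  interiors) — irregular margins and heterogeneous echotexture being the
  canonical malignant signs this class of model exploits;
* `shadow = TRUE` multiplies a trapezoidal band below the mass by 0.35
  (6 px lateral taper);
* CA-125 is log-normal (σ_log = 0.8) with medians 25 (benign), 250
  (malignant, premenopausal) and 150 (malignant, postmenopausal) U/mL, so
  the class-conditional distributions straddle the 200/71 U/mL decision
  thresholds the way elevated-but-unspecific biomarkers do.

Cohorts fix the malignancy count at `round(n · prevalence)` (default
prevalence 0.515, the development cohort's), draw the echotexture mix at
the development cohort's 93:67:79 proportions, make shadows benign-skewed
(30% benign vs 5% malignant) and menopause 62% post. One master seed
derives per-case seeds by a counter, so cohorts are bit-reproducible and
survive partial regeneration.

**What the phantoms do not emulate** — and hence what passing tests do not
show about real data: no point-spread-function physics (no depth-dependent
resolution, no refraction or reverberation artifacts), no probe or
examiner variation in the image itself, no borderline histologies, and
class differences that are by construction separable by the feature
families measured. Synthetic recovery demonstrates that the pipeline's
plumbing, selection and thresholds work; it is *not* evidence of clinical
accuracy.

## 9. Numerical choices and degenerate inputs

* Pixel coordinates are 0-based, pixel-centered, x = column / y = row;
  rasterization is even-odd with half-open crossing intervals, so shared
  boundaries assign each pixel exactly once (a 10×10 unit-spaced square
  rasterizes to exactly 100 px). Masks below 50 px are refused.
* Degenerate cases are defined, not special-cased downstream: constant
  ROIs discretize to level 1; GLCM correlation of a zero-variance channel
  is 1; a degenerate solid subregion falls back to the whole mask.
* Percentages are rounded half-up (base R's banker's rounding would turn
  0.5-ties the wrong way for table reporting).
* Serialization uses full-precision JSON (`digits = NA`).

## 10. Problem sizes used in the checks

The package's own acceptance study simulates train n = 300 / test n = 100
at prevalence 0.5 with 5 contour variants per case, and a 200-phantom
twice-segmented set for the between-operator agreement rate; module tests
use smaller cohorts (24–60) and 96 px frames with proportionally smaller
masses. These sizes give stable estimates for the properties being
asserted (CV sensitivity/specificity ≥ 85% with margin, agreement ≥ 95%)
while keeping the whole suite a matter of minutes; all of them are
package choices and can be scaled up freely through the same functions.

## 11. Known limitations

* The published feature panels behind the per-class counts (269/278/306
  stable features) are not public; this implementation defines the
  catalogue by the IBSI families above and lets stability selection define
  the panels. Counts will differ; behavior, not membership, is the target.
* The original system's trained weights are likewise unavailable — the
  ensemble here is trained on phantoms or on the user's own cohort.
* 2D only, single frame per mass; no Doppler, no 3D, no borderline-tumour
  stratum (the system is deliberately binary).
* The DICOM layer covers uncompressed single-frame little-endian objects
  (monochrome or interleaved RGB), which is what ultrasound secondary
  capture exports in practice; compressed or multi-frame objects are
  rejected with a clear error.
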