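---
title: "Methods: retinal image-quality assessment with hybrid classical features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retinal image-quality assessment with hybrid classical features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Automated retinopathy screening fails silently on ungradable photographs, and
the cause of ungradability matters clinically. Poor quality driven by
acquisition artefacts (motion blur, underexposure) calls for a re-capture or
image enhancement; poor quality driven by ocular pathology — advanced
cataract, central retinal vein occlusion (CRVO), asteroid hyalosis, vitreous
opacity — calls for referral to an ophthalmologist, and re-photographing the
eye wastes time without making the image gradable. `fundusqc` implements a
pipeline that classifies color fundus photographs into *good quality*,
*artefact-associated poor quality* (AAPQ) and *eye-abnormality-associated
poor quality* (EAAPQ), built around four binary tasks: good vs poor, good vs
EAAPQ, good vs AAPQ, and EAAPQ vs AAPQ.

The quality rule is operationalized from two clinically established aspects:

* **visibility** — an image is poor when artefacts or abnormalities cover
  more than 1/4 of the retinal field of view;
* **clarity** — an image is poor when third-order ("level III") vascular
  arches are invisible.

## Pipeline

For each image the pipeline computes a feature vector, selects a sparse
subset of features by penalized maximum likelihood, and classifies:

1. **Field-of-view (FOV) estimation.** Fundus photographs are a bright
   circular retinal field on a dark frame. The mask is estimated by Otsu
   thresholding of luminance (after clipping bright outliers such as the
   optic disc so the threshold separates field from frame, not highlights
   from retina), keeping the largest connected component, closing and
   hole-filling. All area-based rules are relative to this mask, not the
   rectangular frame.
2. **Feature generation** (`extract_features()`), on the green channel
   restricted to the FOV — the green channel carries the highest vessel
   contrast in fundus photography. Blocks, in fixed order:
   *softmax filter-bank embedding* (optional) ‖ *texture* ‖ *fractal* ‖
   *spectral*.
3. **Elastic-net selection** (`fit_elastic_net()`): penalized binomial
   likelihood with mixing `alpha = 0.5`, penalty chosen by cross-validated
   deviance.
4. **Classification**: random forest (500 trees, `sqrt(p)` features per
   split) for the held-out test evaluation; RBF-kernel SVM (`gamma = 1/p`,
   `C = 1`) inside 10-fold cross-validation. Class order is always
   (negative, positive), with `good` positive in the three good-vs-* tasks
   and `eye_abnormality` positive in EAAPQ-vs-AAPQ, so probability 1 is the
   "referral" end of the scale.
5. **Reporting** (`quality_report()`, `crossvalidate()`): confusion counts,
   sensitivity/specificity/accuracy (percent, one decimal; a metric with a
   zero denominator is undefined, not zero), ROC by threshold sweep with
   trapezoidal AUC, and a misclassification breakdown by subtype with
   largest-remainder percent shares that sum to exactly 100.0.

## Feature families

The texture/fractal/higher-order-spectra feature families are implemented as
standard, fully documented representatives; the exact members used by the
original proprietary tooling are not public, so behaviour (not feature-list
identity) is what the test suite pins down.

### Texture (GLCM + first order)

Gray values inside the FOV are quantized to 16 equal-width levels over the
masked range. For each of the four distance-1 offsets (0,1), (1,0), (1,1),
(1,−1) a directed co-occurrence matrix $p(i,j)$ is accumulated over pixel
pairs that both lie in the mask, and summarized by contrast
$\sum (i-j)^2 p$, correlation, energy $\sum p^2$, homogeneity
$\sum p/(1+|i-j|)$ and entropy $-\sum p \log_2 p$ (with $0\log 0 = 0$; the
correlation of a constant image is defined as 0). First-order mean,
variance, skewness, kurtosis (Pearson, $m_4/m_2^2$) and histogram entropy of
the masked pixels are appended once. Each statistic is validated against a
brute-force pairwise-enumeration oracle to $10^{-9}$.

### Fractal

Differential box counting (DBC) treats gray level as surface height: for box
size $s$ on a side-$S$ square, the gray axis is divided into boxes of height
$h = s \cdot 256 / S$ and each $s\times s$ cell contributes
$\lceil \max/h\rceil - \lceil \min/h \rceil + 1$ boxes; the dimension is the
least-squares slope of $\log N(s)$ vs $\log(1/s)$ over dyadic sizes
$s \in [2, \min(S/4, 32)]$. A constant image yields exactly 2. The block
reports the DBC dimension over the full scale range and its fine/coarse
halves, plus the binary box-count dimension of the Otsu-thresholded
foreground (validated on a Sierpinski carpet against
$\log 8/\log 3 \approx 1.893$). Pixels outside the FOV are replaced by the
masked mean before counting, which makes the block invariant to anything
outside the mask.

### Bispectral (higher-order spectra)

Ten 1-D profiles are read from the masked image: row means, column means and
8 radial diameters through the FOV center. Each profile's bispectrum
$B(f_1,f_2) = X(f_1)X(f_2)X^*(f_1+f_2)$ is estimated on the principal domain
($0 \le f_2 \le f_1$, $f_1+f_2 \le n/2$) by averaging over mean-removed,
Hann-windowed segments of length 64 with 50% overlap, and summarized by the
normalized bispectral entropy $P_1 = -\sum p\log p / \log n_{cells}$ with
$p = |B| / \sum |B|$, the squared-magnitude entropy $P_2$, the mean
magnitude, and the entropy of the phase histogram (16 bins). An all-zero
bispectrum (constant profile) has all summaries defined as 0. Profiles
shorter than one segment are zero-filled so the block layout never varies;
an image on which *every* profile is too short is an error. The estimator is
validated against a direct triple-product DFT oracle.

### Softmax filter-bank embedding (optional)

The deep block is a deterministic, training-free 1000-entry descriptor
shaped like a classification-layer activation: multi-scale oriented
frequency-domain Gaussian band energies (4 scales × 8 orientations × 3
channels, computed via Parseval's identity), plus channel moments, projected
through a fixed-seed random linear map and a softmax. Entries are
non-negative and sum to 1, and the map is a pure function of the image. It
is disabled by default; the synthetic benchmark uses classical features
only.

## Choosing the penalty

The elastic-net penalty is chosen by 10-fold cross-validated deviance. The
package default is the **one-standard-error rule** (largest penalty within
one SE of the deviance minimum) rather than the raw minimum, and this choice
is backed by a calibration experiment reproduced in the test suite: with 100
pure-noise features and permuted labels (n = 500), the raw minimum chases
fold noise — deviance "improvements" of 0.003–0.008, within one SE — and
admitted up to 24 spurious features in 4 of 10 permutation seeds (averaging
the CV curve over five fold assignments does not help, because the spurious
correlations live in the data, not the folds). The 1-SE rule selected at
most 3 spurious features in 10/10 seeds while still recovering all five
planted informative features (logit effect 2.0). `lambda_rule = "min"`
remains available. When no coefficient is nonzero at the chosen penalty the
selection falls back to the largest penalty at which a first feature enters,
so the selected set is never empty.

Standardization statistics, the selection and the classifier are always
computed on training data only; `crossvalidate()` re-runs the whole chain
inside every fold and pools out-of-fold predictions into a single confusion
matrix — the convention matching a single reported Se/Sp/Acc per
cross-validation experiment.

## The synthetic generator

No external image set ships with the package; `render_fundus()` +
`apply_degradation()` + `generate_dataset()` produce labelled test data.

A scene is a circular FOV (radius `image_size/2 − 1`, so the field fills
≈ π/4 of the frame) with a vignetted, softly textured retinal background, a
bright optic disc on the horizontal midline, and a recursive binary
branching vessel tree: 4 roots leaving the disc, 6 jittered segments per
branch, child angle 20–35°, length and width decaying by 0.72 per order,
defaults of 4 orders. Branch orders are recorded per pixel, because the
clarity rule is evaluated on order-3 branches: their **Michelson contrast**
(green channel, vessel pixels vs a local background ring excluding all
vessels and the disc) must stay at or above **0.02** for the arches to count
as visible. "Level III arches are visible" is a clinical judgement; this
contrast threshold is the package's operationalization of it.

Six degradations are modelled, each with `severity` ∈ [0, 1] (0 = identity,
pixel-exact) and, for region-forming kinds, a `coverage_target`:

* **blur** — Gaussian low-pass, σ = severity × 0.03 × image side. Chosen so
  the order-3 contrast crosses the 0.02 visibility threshold mid-range
  (severity ≈ 0.45 at 256 px), leaving borderline cases on both sides.
* **underexposure** — luminance factor
  $(1-s)\,(1 - 0.8\,s\,m(x))$ with $m$ a soft half-plane shadow whose
  hard area equals the coverage target; severity 1 extinguishes the FOV
  entirely. A pixel counts as *covered* when its factor falls below 0.15
  (near-black); global darkness beyond severity 0.85 covers everything.
* **cataract** — veiling luminance plus contrast loss:
  $x \mapsto (1-c)x + c\cdot\text{veil}$, $c = 0.75\,s\,(0.25+0.75m)$ with a
  calibrated soft blob $m$; the veiled region counts as covered once peak
  opacity reaches 0.35 (severity ≥ 0.47).
* **crvo** — widened, darkened vessels plus dark flame-shaped elliptic blobs
  seeded on jittered vessel-centerline points, accumulated until the hard
  occlusion mask reaches the coverage target.
* **asteroid hyalosis** — many small bright near-circular particles
  (radius 2–5.6 px at 256), accumulated to the coverage target.
* **vitreous opacity** — diffuse translucent dark patches; a pixel counts
  as occluded when cumulative opacity reaches 0.4.

The label rule (`label_from_provenance()`, also applied incrementally by
`apply_degradation()`): an image is **poor** when any degradation's rendered
coverage exceeds 1/4 of the FOV or the order-3 contrast first falls below
0.02 at some step; the subtype is the family of the triggering degradation,
and when both families trigger, the tie breaks toward `eye_abnormality`
(missing a referable abnormality is the costlier error). Everything is a
pure function of parameters and seeds; datasets regenerate bit-identically.

`generate_dataset()` matches requested class counts exactly by rejection:
severities are drawn from ranges wide enough to span the label thresholds
(good class: half the images carry one mild degradation, severity
0.05–0.35, coverage 0.03–0.18; artefacts: severity 0.30–0.95, shadow
coverage 0.30–0.60; abnormalities: severity 0.30–0.90, coverage 0.18–0.45),
and a candidate whose realized label disagrees with its class is redrawn
with a new derived seed. Degradation kinds rotate deterministically within
each class, emulating a mixed clinical composition. These ranges were fixed
once, as plausibly wide spreads around the thresholds; they are
configuration, not empirical estimates.

### What the generator does and does not emulate

It reproduces the *structure* that the quality rules and features respond
to: a circular field, an ordered vessel hierarchy whose fine branches vanish
under blur, occluders with controlled area, global luminance and contrast
degradation. It does **not** attempt photorealism, camera optics, retinal
lesions, or the long-tailed variability of clinical photographs. Passing
the synthetic benchmark therefore demonstrates that the pipeline's
machinery — features, selection, classification, evaluation — works end to
end and separates the modelled degradation classes; it does not certify
clinical performance on real images, which requires large expert-labelled
clinical datasets.

## Problem sizes and numerical choices

* The bundled benchmark uses 450 images (150 per class) at 256 px — sizes
  chosen to exercise every degradation kind and both poor classes at
  desk scale. Unit fixtures are 64–256 px.
* GLCM: 16 levels, 4 offsets at distance 1. Bispectrum: segment length 64,
  50% overlap, Hann window. Fractal: dyadic box sizes in `[2, min(S/4, 32)]`
  on a centered square crop whose side is a multiple of 32 (16 below
  128 px); at least 3 scales are required.
* Ties in scores: ROC thresholds and hard labels both use ≥, so the
  trapezoidal AUC equals the Mann–Whitney statistic with ties counted half.
* SVM probabilities are a logistic transform of the decision values rather
  than Platt scaling: Platt's internal cross-validation is not seeded
  reproducibly across platforms, while the logistic transform is
  deterministic, preserves the ranking (hence the ROC and AUC), and keeps
  the 0.5 probability cut at the decision boundary.
* Degenerate inputs: constant images are rejected by the FOV estimator;
  constant feature columns are dropped with a warning before selection;
  classes smaller than the fold count are an error suggesting a smaller k.

## Known limitations

* The deep branch is a fixed filter-bank embedding, not a trained network;
  it stands in for a pretrained backbone's softmax layer shape-wise, not
  semantically.
* The FOV estimator assumes a dark frame around a brighter field; it will
  mis-segment images with bright borders.
* `stratified_split()` stratifies by (label, poor-subtype) only, and splits
  by image — eye-level or patient-level grouping is out of scope.
* CRVO rendering increases vessel width and adds haemorrhage-like blobs but
  does not re-route vessel geometry (no true tortuosity change).
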