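# fundusqc

Quality assessment for color fundus photographs, with a clinically motivated
twist: poor-quality images are not one class. **Artefact-associated poor
quality** (AAPQ — motion blur, underexposure) is fixable by re-photographing
the eye; **eye-abnormality-associated poor quality** (EAAPQ — advanced
cataract, central retinal vein occlusion, asteroid hyalosis, vitreous
opacity) is not, and the patient should be referred instead. `fundusqc`
classifies images into good / AAPQ / EAAPQ via four binary tasks
(good vs poor, good vs EAAPQ, good vs AAPQ, EAAPQ vs AAPQ), so a screening
program can route each ungradable image to "re-capture" or "refer".

The package is aimed at people building or studying screening pipelines:
it contains the full method, an evaluation stack, and a seeded synthetic
fundus generator, so everything is reproducible without any external image
dataset.

## Method

An image is labelled *poor* when artefacts or abnormalities cover more than
1/4 of the retinal field of view, or when third-order (level III) vascular
arches are invisible — operationalized as the Michelson contrast of order-3
vessel pixels against their local background falling below 0.02.

Per image the pipeline computes a hybrid feature vector and classifies:

- **Texture**: gray-level co-occurrence matrices at four distance-1 offsets
  (16 levels over the masked range) summarized by contrast Σ(i−j)²p(i,j),
  correlation, energy Σp², homogeneity Σp/(1+|i−j|), entropy −Σp log₂p,
  plus first-order moments of the masked histogram.
- **Fractal**: differential box-counting dimension of the gray-level
  surface (slope of log N(s) vs log 1/s; exactly 2 for a constant image)
  over full/fine/coarse scale ranges, plus the binary box-count dimension
  of the Otsu foreground.
- **Higher-order spectra**: the bispectrum B(f₁,f₂) = X(f₁)X(f₂)X*(f₁+f₂)
  of ten 1-D profiles (row means, column means, 8 radial diameters),
  summarized by normalized bispectral entropies P₁ and P₂, mean magnitude
  and phase entropy.
- Optionally, a deterministic 1000-entry **softmax filter-bank embedding**
  (oriented multi-scale band energies → fixed random projection → softmax).

Features are then filtered by **elastic-net penalized logistic regression**
(glmnet, α = 0.5, penalty by cross-validated deviance with the 1-SE rule)
and classified by a **random forest** (500 trees) for held-out testing and
an **RBF SVM** inside pooled, leakage-free **10-fold cross-validation**.
Reports include confusion counts, sensitivity/specificity/accuracy, ROC/AUC
(trapezoidal ≡ Mann–Whitney), and a misclassification breakdown by subtype
with largest-remainder percent shares.

See `vignette("quality-assessment-methods")` for models, parameters and
design rationale.

## Worked example

```r
library(fundusqc)

# render a synthetic fundus and degrade it
img <- render_fundus(scene_params(image_size = 256, rng_seed = 7))
img
#> <fundus_image> 256x256  label=good  degradations=0

degraded <- apply_degradation(
  img, degradation("cataract", severity = 0.8, coverage_target = 0.3, rng_seed = 1))
degraded
#> <fundus_image> 256x256  label=poor  subtype=eye_abnormality (cataract)  degradations=1
```

The cataract's veil covers 30% of the field of view — over the 1/4
threshold — so the label flips to poor with subtype `eye_abnormality`.

```r
# a labelled dataset, features, and pooled 10-fold CV for good-vs-poor
m <- generate_dataset(dataset_spec(n_good = 40, n_artefact = 40, n_eye_abnormality = 40),
                      out_dir = "demo", rng_seed = 11)
feats <- extract_features_batch(m, feature_config())
X <- as.matrix(feats[, -1])
y <- ifelse(m$label == "good", "good", "poor")

cv <- crossvalidate(X, y, k = 10, kind = "svm", positive_class = "good", rng_seed = 3)
cv
#> <fqc_cv> 10-fold, svm, pooled:
#> <fqc_report> Se 85.0%  Sp 100.0%  Acc 95.0%  AUC 0.976  (n = 120)
```

Sensitivity is the fraction of good images recognized as good (34/40 here),
specificity the fraction of poor images recognized as poor (80/80), pooled
over all ten held-out folds; each fold re-runs standardization, selection
and the SVM on its own training part. The elastic net keeps less than half
of the classical features:

```r
sel <- fit_elastic_net(X, y, positive_class = "good", rng_seed = 3)
sel
#> <fqc_selection> 28/69 features selected at lambda = 0.022115 (alpha = 0.50)
```

`run_pipeline(run_config(...))` chains all stages (synthesis → features →
stratified 70/30 split → per-task selection + RF test report + SVM CV
report → optional external validation) and writes a summary table; the
`inst/scripts/aria` script exposes the same stages as shell subcommands
(`aria synth`, `aria split`, `aria extract`, `aria train`, `aria cv`,
`aria eval`, `aria run`).

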