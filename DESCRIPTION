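Package: fundusqc
Title: Retinal Fundus Image Quality Assessment with Hybrid Texture,
    Fractal and Bispectral Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses the quality of color fundus photographs and
    distinguishes artefact-associated poor quality (blur, underexposure;
    fixable by re-capture) from eye-abnormality-associated poor quality
    (cataract, central retinal vein occlusion, asteroid hyalosis, vitreous
    opacity; warrants referral). Implements a feature-generation stage
    combining gray-level co-occurrence texture statistics, differential
    box-counting fractal dimensions, bispectral (higher-order spectra)
    entropies and an optional deterministic softmax filter-bank embedding;
    elastic-net penalized-likelihood feature selection; random-forest and
    support-vector-machine classification with stratified splits and
    pooled k-fold cross-validation; and full evaluation reporting
    (confusion matrices, sensitivity/specificity/accuracy, ROC/AUC,
    misclassification breakdowns). Ships a seeded synthetic fundus
    generator (circular field of view, branching vessel tree, optic disc,
    parameterized degradations) so the whole pipeline is testable without
    external image datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    e1071,
    generics,
    ggplot2,
    glmnet,
    grDevices,
    jsonlite,
    png,
    randomForest,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    jpeg,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
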