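# histospectra

Quantitative histopathology feature mining with hyperspectral association
analysis, for squamous neoplasia of the tongue.

## The problem

Hyperspectral imaging (HSI) measures a reflectance spectrum at every pixel
of a tissue surface and can separate neoplastic from normal mucosa, but the
microscopic basis of that spectral difference is not obvious. One way to
probe it is to quantify the architecture of the matching H&E histology —
nuclear size, shape, crowding, texture, epithelial organisation — select the
features that best discriminate normal from neoplastic tissue, and then ask
which of them co-vary with the measured reflectance spectra.

`histospectra` implements that pipeline end to end for R users:

1. **Segmentation.** The epithelium is segmented from the red channel
   (edge-preserving median smoothing, global Otsu threshold, hole filling,
   morphological opening). Within it, k-means on RGB separates nuclei,
   cytoplasm and background by colour semantics. Nuclear clusters are split
   by repeated colour re-clustering (components with solidity < 0.9 and
   > 500 px) and by marker-controlled watershed on the blue-ratio image
   `[B/(1+R+G)]/(1+R+G+B)` (components > 150 px, solidity < 0.9, applied
   twice). False detections are removed by red/blue ratio rules (1.2 during
   splitting, 1.0 at finalisation), small fragments by 50/25 px thresholds,
   and each nucleus receives a moment-based fitted ellipse.
2. **Feature bank.** 712 features per crop: for each of epithelium,
   cytoplasm and nuclei, 71 colour features (transformed-RGB histograms and
   red–blue difference statistics after removing white pixels with
   luminance Y > 180) and 149 texture features (19 GLCM/Haralick at 64 grey
   levels over 16 offsets, 56 Gabor energies/entropies from a 28-filter
   bank, 10 rotation-invariant uniform LBP bins, 64 segmentation-based
   fractal texture features from a multi-level-Otsu decomposition); plus,
   for nuclei, 44 morphometric and 8 Delaunay-topology features.
3. **Selection and modelling.** Greedy mRMR ranking by mutual information
   (maximise `I(feature; class) − mean I(feature; selected)`), then an
   SVM-RBF classifier tuned by nested leave-one-subject-out
   cross-validation (per-fold selection and standardisation; no leakage).
4. **Spectra.** Hypercubes (450–900 nm, 5-nm steps) are calibrated to
   relative reflectance, `(raw − dark) / (white − dark)`, and per-pathology
   spectral signatures are averaged under a line-based pathology map.
5. **Association.** Spearman rank correlation between the selected features
   and the signatures, with per-cell significance at α = 0.05 and
   green/red/white heatmap rendering.

Because real cohorts of this kind are not publicly deposited, the package
ships a synthetic-data module that renders H&E-style crops (blue-purple
nuclei on pink cytoplasm, grade-dependent density, size, irregularity and
crowding) with exact ground truth, plus matching hyperspectral cubes with
white/dark references and a haemoglobin-like dip near 540 nm. Every stage
of the pipeline is tested against that ground truth.

## Worked example

```r
library(histospectra)

# one synthetic carcinoma crop with ground truth
crop  <- generate_he_image(tissue_spec("carcinoma", seed = 7))
masks <- segment_tissue(crop$image)
masks
#> <tissue_masks> 208 x 320, 42 nuclei, epithelium 64.9%
nrow(crop$truth$nuclei)   # ground truth
#> [1] 42

features <- extract_features(crop$image, masks)
nrow(features)
#> [1] 712
dplyr::count(features, compartment)
#> # A tibble: 3 x 2
#>   compartment     n
#>   <chr>       <int>
#> 1 cytoplasm     220
#> 2 epithelium    220
#> 3 nuclei        272
```

The printed nucleus count matches the ground truth, and the feature table
carries 220 + 220 + 272 = 712 named, compartment-tagged values.

A full study — synthetic cohort, segmentation, features, nested CV,
signatures, association — runs from one configuration:

```r
run <- run_end_to_end(run_config(
  seed = 1,
  grid = cv_grid(m = c(1, 5, 10, 30), cost = 2^c(-1, 1, 3),
                 gamma = 2^c(-5, -3, -1))
))
run$cv
#> <cv_report> 10 folds, 40 samples
#> accuracy 0.950, sensitivity 0.933, specificity 1.000
glance(run$cv)
autoplot(run$association)   # green/red/white Spearman heatmap
```

Accuracy 0.95 here means 38 of the 40 held-out images of the synthetic
cohort were classified correctly by models that never saw their subject
during training or tuning.

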