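---
title: "Methods: from H&E architecture to spectral signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from H&E architecture to spectral signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and procedures, the parameters that matter, what the synthetic
data do and do not emulate, and the design choices made where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The pipeline in one paragraph

Squamous neoplasia remodels the tongue epithelium: nuclei proliferate,
enlarge, become irregular and crowd into nests, and the epithelial band
thickens. Those architectural changes scatter light differently, so the
reflectance spectrum measured over the tissue surface by hyperspectral
imaging (450–900 nm in 5-nm steps here) carries diagnostic information.
The pipeline quantifies the architecture from H&E crops (segmentation, a
712-dimensional feature bank), selects discriminative features (mRMR),
validates them in a nested leave-one-subject-out SVM-RBF harness, calibrates
hypercubes to relative reflectance and extracts per-pathology signatures,
and finally correlates selected features with the signatures by Spearman
rank correlation with per-cell significance at α = 0.05.

## Segmentation model and its constants

The cascade and all its constants live in `segmentation_params()`:

* **Epithelium.** The red channel has the best epithelium/background
  contrast in H&E. It is smoothed with a median filter (radius 9 px by
  default), a classic edge-preserving smoother: it suppresses isolated
  nuclei so the band thresholds as one region while leaving the band edge
  in place, which a linear Gaussian would blur. A global Otsu threshold
  follows, with polarity fixed so the darker (stained) side is tissue; then
  hole filling, an opening (disc radius 5) to remove spurious specks, and a
  re-fill so the returned mask is hole-free by construction.
* **Compartments.** k-means (k = 3, Euclidean, on RGB) with deterministic
  initial centres at the mean colours of the luminance terciles. Roles are
  assigned by colour statistics rather than cluster index (k-means ordering
  is arbitrary): nuclei = highest mean blue-ratio, background = brightest
  remaining, cytoplasm = the rest. For images with more than 20 000
  epithelial pixels the centres are fitted on a deterministic subsample and
  all pixels are assigned to the nearest centre; the result is unchanged on
  separable palettes and the run time roughly halves.
* **Cleanup.** Fill holes, dilate (disc r = 2), open (disc r = 4), discard
  components under 50 px. Structuring elements are exact Euclidean discs
  (lattice points with x² + y² ≤ r²), so the radius-4 disc has exactly
  49 px — the smallest opening-invariant component — which is what makes
  the under-50-px rule a real constraint rather than dead code.
* **Cluster splitting.** Large clusters (solidity < 0.9 *and* area
  > 500 px) are re-clustered in colour space (k = 2, initialised at the
  component's blue-ratio extremes); the less-blue group (rims, overlap
  pixels) is removed, disconnecting the darker chromatin cores. The loop
  repeats until no trigger remains, capped at 20 iterations (the cap is a
  termination guarantee; a warning reports it). Then red/blue > 1.2
  components are removed as false detections, holes filled, < 25 px
  dropped. Small clusters (> 150 px, solidity < 0.9) are split twice by
  marker-controlled watershed on the median-smoothed blue-ratio image —
  markers are its regional maxima, shallow maxima suppressed by a tolerance
  of 0.05 on the [0, 1]-normalised landscape — cutting one-pixel seams
  between regions; fragments below 50 px are discarded. The 50-px discard
  applies to fragments of split components, not globally, so 25–49 px
  nuclei legitimately retained by the large-cluster stage survive. The
  trigger is re-evaluated on the updated mask in the second pass.
* **Finalisation.** Components with mean red/blue above 1.0 are removed
  (red/blue uses 8-bit values with denominator `max(B, 1)` so the stated
  1.2/1.0 cut points are preserved without division by zero); survivors
  get a moment-based ellipse fit (second central moments with the 1/12
  pixel-variance correction; axes 4·√eigenvalue) as their smooth contour.

## The feature bank (712 = 220 + 220 + 272)

Per compartment: 71 colour features (pixels with YCbCr luminance Y > 180
removed first; transformed-RGB `(X − μ)/σ` 16-bin histograms per channel on
a fixed [−3, 3] range, making the block gain- and shift-invariant; a 16-bin
red−blue difference histogram plus seven statistics) and 149 texture
features: 19 GLCM statistics (64 grey levels by min–max rescaling; 16
symmetric co-occurrence matrices, four directions × distances 1–4,
averaged; the 13 Haralick statistics plus autocorrelation, cluster
prominence, cluster shade, dissimilarity, inverse difference, maximum
probability — "cluster shade" adopted as the standard name), 56 Gabor
features (4 orientations × 7 radial frequencies doubling from 2√2 to 128√2
cycles per image width; frequency-domain Gaussian transfer with ~1-octave
bandwidth, σ_f = f₀/3; entropy and mean-square energy of each magnitude
image), 10 rotation-invariant uniform LBP bins (P = 8, R = 1 on the
8-neighbour ring), and 64 mSFTA features. Nuclei additionally contribute
44 morphometric features — seven statistics of six per-nucleus descriptors
(area, major/minor axis, solidity, eccentricity, compactness
perimeter²/(4π·area)) plus a single mean neighbourhood radius (half the
nearest-centroid distance) and the nucleus-to-cytoplasm area ratio — and 8
Delaunay features ({mean, max, min, disorder} of triangle area and
perimeter, disorder = 1 − 1/(1 + σ/μ)).

The morphometric count resolves an arithmetic tension: seven statistics of
all seven descriptors plus the N:C ratio would give 50, not 44; the only
reading consistent with both the 44 figure and the 712 total is full
statistics for six descriptors plus scalar neighbourhood radius and N:C,
which is what is implemented.

**mSFTA.** Multi-level Otsu (n_t = 4 thresholds, exact dynamic programme
over the 256-bin histogram maximising between-class variance) yields two
sets of binary images: {I > t_i} and the contiguous bands
{t_i < I ≤ t_{i+1}} with the maximum grey value closing the last band —
8 images; the last band image coincides with the last one-threshold image,
as in the original segmentation-based fractal texture analysis. From each,
a boundary (pixels 4-adjacent to background) and a morphological skeleton
are taken. The skeleton is the classical union over k of
`erode_k(X) \ open(erode_k(X))` for the cross element, computed in closed
form as the local maxima of the city-block distance transform (provably
identical, and one distance map instead of hundreds of erosions). Each of
the 16 derived images contributes its box-counting fractal dimension and
pixel count plus the mean intensity and Shannon entropy (base 2, 256-bin)
of the grey image under it.

**Box counting.** N(s) is the minimal number of s × s boxes covering the
foreground, minimised over grid offsets (the box dimension is defined via
minimal covers), with s on a geometric ladder of powers of three up to a
third of the short image side; the dimension is the least-squares slope of
log N against log 1/s. The triadic ladder keeps box sizes commensurate with
self-similar test patterns: a depth-4 Sierpiński carpet measures
log 8/log 3 ≈ 1.893 on it, whereas dyadic boxes on the same finite pattern
are biased low (≈ 1.72) because no dyadic scale aligns with the carpet's
holes. Lines measure ≈ 1 and filled squares ≈ 2 on either ladder.

Degenerate inputs (empty masks, constant regions, fewer than three
non-collinear centroids, a single nucleus) yield zeros with per-feature
validity flags rather than `NaN`, so selection and cross-validation never
ingest non-finite values. Feature names are
`{compartment}.{family}.{name}` with a stable order, asserted to total 712
(220/220/272) at run time.

## Selection and modelling

Mutual information uses the histogram plug-in estimator: continuous
variables are discretised by equal-frequency binning into
min(10, ⌈√n⌉) bins (equal-frequency is invariant to monotone transforms,
and the bin cap keeps the estimator sane at the fold sizes used here);
discrete variables are used as-is; the base is 2 (bits; base only rescales
and cannot reorder candidates). The greedy mRMR rule selects, at each
step, the feature maximising `I(feature; class)` minus the mean mutual
information with the already-selected set — the difference (MID) form —
with ties broken toward the lowest column index. The test suite verifies
the greedy path against a brute-force oracle on fixtures of up to 20
features.

The nested harness leaves one subject out in the outer loop and one
remaining subject out in the inner loop; mRMR ranking and z-scoring are
fitted on inner-training data only; the (m, cost, γ) triple with the best
mean inner accuracy — ties toward smaller m, then cost, then γ — is refit
on the outer-training set. The canonical grid (m up to 342, cost and γ in
2^{−5..5}) is the `cv_grid()` default; the synthetic studies in the tests
and acceptance script use a reduced grid (m ∈ {1, 5, 10, 30}, cost
∈ 2^{−1,1,3}, γ ∈ 2^{−5,−3,−1}) sized to the 40-image cohorts they run on.
The SVM itself is libsvm via `e1071`; the bespoke content is the harness,
the per-fold selection and the leakage guarantees, which the tests assert
directly (held-out subjects never intersect their training folds, and
perturbing a held-out subject's features leaves all other folds'
predictions bit-identical).

## Spectra and association

Calibration is `(raw − dark)/(white − dark)` voxel-wise; non-positive
denominators are masked as `NA` rather than propagated (an infinity would
poison every mean it touches), and reflectance above 1 (specular) is kept,
not clipped. Signatures average the unmasked pixels of each pathology
class under a line-based map; classes absent from the map are omitted.

Association uses Spearman's rank correlation per (feature, wavelength)
pair with the two-sided t-approximation p-value (an exact small-n option
exists via `cor.test`); no multiple-testing correction by default, matching
the per-cell α = 0.05 convention, with Benjamini–Hochberg available. The
sample unit is the (subject, pathology class) pair with class-mean features
and signatures — pixel-level units would pseudo-replicate within a
subject. Heatmap cells are positive-significant (green),
negative-significant (red) or nonsignificant (white); rows with
|mean ρ| ≥ 0.5 are flagged strong.

## What the synthetic data emulate — and what they do not

`tissue_spec()` renders an epithelial band (top fraction of the crop) of
pink cytoplasm with a few unstained white spaces, nuclei as filled
perturbed ellipses (sinusoidal radial perturbation, amplitude =
irregularity × minor axis, 3–7 lobes) with a radial brightness ramp from a
darker core to a brighter rim, and a near-white region below the band.
Grade defaults follow the qualitative ordering of neoplasia: from normal
to carcinoma the band fraction rises 0.45 → 0.65, nucleus count 22 → 42
(on the default 320 × 208 crop), axes (19, 13) → (22, 15) px, boundary
irregularity 0.05 → 0.35 and crowding 1.0 → 2.0. `effect_size`
interpolates every class toward the normal parameters (0 = labels
uninformative). Crowding sets the minimum centroid spacing to
1.5 · mean axis / crowding and, above 1, seeds new nuclei near existing
ones with probability 1 − 1/crowding, emulating proliferating nests; both
mechanisms shorten nearest-centroid distances monotonically.

Several rendering choices are load-bearing for the fixed segmentation
constants. Nuclei are sized like 20×-magnification nuclei (≈ 200–260 px)
because the 500/150/50/25 px thresholds and disc radii 2/4 presuppose that
scale. The palette — nuclei (120, 80, 160), cytoplasm (198, 140, 162),
background (250, 240, 245) — keeps nuclei blue-dominant (red/blue 0.74,
highest blue-ratio), cytoplasm above the 1.2 red/blue artifact cut, and,
critically, makes tissue-versus-background the dominant mode of the red
histogram so the global Otsu threshold lands between band and background;
with very dark nuclei the nuclei-versus-rest gap dominates instead and the
same algorithm returns a nuclei mask. The brightness-ramp shading keeps
red/blue constant inside each nucleus (so the R/B ≤ 1 retention rule holds
even after the r = 2 dilation adds a ring of cytoplasm pixels) while
giving the blue-ratio landscape exactly one regional maximum per nucleus —
the marker the watershed needs.

Spectra are a logistic-rising baseline (0.25 + 0.75·logistic((λ−580)/60))
times a class amplitude (normal 0.35 → carcinoma 0.55, background 0.08)
minus a Gaussian dip at 540 nm (width 25 nm, depth 0.35) where haemoglobin
absorbs; reference cubes have smoothly varying illumination and offset,
and raw = dark + reflectance·(white − dark) + noise, so zero-noise
calibration inverts generation exactly. Subjects carry mild (≈ 5%)
multiplicative random effects on density and amplitude so
leave-one-subject-out folds differ genuinely.

Not emulated: stain variability and deconvolution, scanner artifacts,
stroma and muscle substructure, specular glare, spatial registration
between cube and histology beyond the supplied line map, and tissue
optics (absorption/scattering coefficients). Passing tests therefore show
that the algorithms recover known architecture and spectra under H&E-like
colour semantics — not that they are robust to real-slide variability.

## Problem sizes

The synthetic studies use 320 × 208 crops, 10 subjects × 4 classes × 1
image (40 images per cohort), 36 × 36 × 91 cubes, and the reduced grid
above; the association sign check runs ten such cohorts. These sizes give
stable statistics (≈ 20–40 nuclei per crop, 40 (subject, class) units per
correlation) while keeping a full study in the minutes range on one CPU.

## Known limitations

* The box-counting estimate is scale-limited on small masks; boundary
  images of a 320-px-wide band span barely two decades of box size, so
  absolute dimensions carry ±0.1-level uncertainty (the closed-form tests
  use that tolerance).
* The permutation-style chance-level control for the CV harness uses
  synthetic feature matrices; image-level permutation runs would cost an
  order of magnitude more for the same inferential content.
* Spearman p-values use the t approximation; at n = 40 units this is
  accurate, but for much smaller designs the exact option should be used.
* The Lantuéjoul-style skeleton is not guaranteed connected (a known
  property of the morphological skeleton); skeleton-based features are
  statistics of the pixel set, so connectivity is not relied upon.
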