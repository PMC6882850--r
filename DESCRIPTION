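Package: histospectra
Title: Quantitative Histopathology Feature Mining with Hyperspectral
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for linking microscopic tissue
    architecture to macroscopic optical measurements in squamous neoplasia
    of the tongue. Segments H&E-stained epithelium into nuclei, cytoplasm
    and background with a k-means and marker-controlled watershed cascade;
    extracts a 712-dimensional bank of colour, texture (GLCM, Gabor, local
    binary pattern, segmentation-based fractal), morphometric and
    Delaunay-topology features per compartment; ranks features by
    minimal-redundancy maximal-relevance (mRMR) mutual information; trains
    normal-versus-neoplastic classifiers under nested leave-one-subject-out
    cross-validation with RBF support vector machines; calibrates
    hyperspectral cubes (450-900 nm) to relative reflectance against white
    and dark references and extracts per-pathology spectral signatures;
    and quantifies feature-spectrum association with Spearman rank
    correlation heatmaps. A synthetic-data module generates paired
    H&E-style crops with ground truth and matching hyperspectral cubes so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    deldir,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
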