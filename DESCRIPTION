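Package: foldshape
Title: Quantification of Anisotropic Cell Shape, Microtubule Comets and
    Region Intensities in Folding Neuroepithelia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying three-dimensional neuroepithelial cell
    shape during basal tissue folding, as at the zebrafish
    midbrain-hindbrain boundary. Implements orthogonal-slice morphometry
    (cell length, apical/basal digital xz slices at one-sixth positions,
    maximal depth chord within 45 degrees of the z-axis, perpendicular
    width, and the x:z anisotropy ratio), ROI-based intensity
    normalizations for filament reporters and immunostains, an EB3 comet
    pipeline (Otsu particle analysis, Laplacian-of-Gaussian sub-pixel
    detection, linear-motion predictive linking, per-track speed), a
    statistical layer (Welch's t, batch-adjusted one-way ANOVA, Tukey
    HSD), and a synthetic-data generator producing folded pseudostratified
    epithelium stacks and comet movies with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
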