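Package: lumentopo
Title: Topology and Shape Morphometrics of Epithelial Lumen Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the topology and geometry of epithelial lumen
    networks in 3D image stacks of neuroepithelial organoids. Provides a
    synthetic-data generator with known ground truth (spheres,
    spherocylinders, tori, wiffle balls, and fusion time series), volume-wise
    Otsu and multi-Otsu segmentation, watertight triangle-mesh extraction by
    marching tetrahedra, per-lobule morphometrics (volume, area, integral
    mean curvature, Euler characteristic, genus, reduced volume and reduced
    curvature), counters for trans and cis epithelial fusion events,
    discrete Helfrich bending-energy estimation as a function of the reduced
    Gaussian rigidity, and shape-diagram guide curves for spherocylinder and
    wiffle-ball morphologies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    tiff,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
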