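Package: nanofoci
Title: Nanoscale Spatial Analysis of Meiotic DSB Repair Foci from
    Single-Molecule Localization Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of RAD51 and DMC1 accumulation at meiotic
    double-strand-break repair foci across imaging scales. At confocal scale:
    prominence-based focus detection, synaptonemal-complex mask filtering,
    nearest-neighbour distance statistics and Kolmogorov-Smirnov comparison
    against mask-constrained random placement. At single-molecule (dSTORM)
    scale: region-of-interest management and quality control, kernel-density
    segmentation of localisation clouds into nanofoci, DxRy configuration
    labelling, inter-nanofocus distance and morphology analytics, axis
    distances, rotation-based consensus alignment, and a generative
    three-dimensional D2R1 model with grid simulation and least-squares
    fitting of its length and angle parameters. Includes a synthetic-data
    generator emulating the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    Rcpp,
    minpack.lm,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    KernSmooth,
    withr
Config/testthat/edition: 3
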