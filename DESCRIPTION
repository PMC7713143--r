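Package: callusmorph
Title: Micro-CT Callus Morphometry and Torsional Biomechanics for Plated
    Osteotomy Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis pipeline for plated long-bone osteotomy
    healing studies. Generates calibrated synthetic micro-CT phantoms of an
    osteotomized cortical shaft with periosteal callus compartments of known
    volume and mineral density, segments bone and callus by density
    thresholding with morphological mask refinement and slice-wise
    reassignment of highly mineralized callus, computes morphometric outcomes
    (compartment volumes, mean densities, cis/trans callus distribution,
    cross-sectional polar moment of inertia profiles), extracts stiffness,
    yield, ultimate torque, rotation and energy to failure from torque-angle
    torsion curves, and compares treatment groups with one-way ANOVA and
    Tukey post-hoc tests computed either from raw data or from published
    summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
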