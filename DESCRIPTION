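Package: hiptomo
Title: Desk-Scale Hierarchical Phase-Contrast Tomography Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates propagation-based phase-contrast tomography scans of
    synthetic organ phantoms in the acquisition geometries used for
    hierarchical phase-contrast tomography (HiP-CT) of whole human organs:
    parallel-beam line integrals, Fresnel free-space propagation, detector
    accumulation, photon noise, half and quarter extended field-of-view
    acquisition, vertical scan series, and reference-jar scans for local
    tomography. Reconstructs them with the matching processing chain
    (reference flat-fielding, vertical-profile residual subtraction,
    single-distance phase retrieval with unsharp masking, extended
    field-of-view sinogram stitching, filtered back-projection, ponderate
    vertical concatenation, 16-bit conversion, ring and stripe artefact
    correction). Scores image quality with Fourier shell correlation and the
    1/2-bit resolution criterion, signal-to-noise ratio, structural
    similarity, and histogram statistics, and performs quantitative biology
    on binary volumes: thresholding, chamfer distance maps, local thickness,
    surface-area-to-volume, Euler connectivity, object morphometry,
    virtual-biopsy stereology and grouped comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tibble,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
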