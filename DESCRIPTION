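Package: pelletscan
Title: Whole-Slide Morphometry of Mycelial Pellets and Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, separates, filters and quantitatively describes
    mycelial particles (pellets and fragments) of filamentous microorganisms
    in phase-contrast whole-slide micrographs. Assembles tile grids into
    calibrated mosaics with background-based brightness normalization,
    segments candidate particles by dual-sided thresholding, hole filling,
    blurred-mask watershed with an interface-length re-merge rule, Voronoi
    border subtraction and size filtering, and computes a full per-particle
    descriptor vector: area, intensity statistics, fitted-ellipse shape
    descriptors, maximum Feret diameter by rotation, roughness, morphology
    number, box-counting fractal dimensions, polar circularity, 20-band
    radial intensity profiles, halo width and density ratio. Includes a
    synthetic phase-contrast slide generator with pixel-exact ground truth,
    declarative rule-set particle filters, and population-level reporting
    with confidence ellipses and two-sample comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
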