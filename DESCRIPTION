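Package: ruplaque
Title: Ruthenium-106 Ophthalmic Plaque Dosimetry and Tilted-Placement Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dose calculation and placement planning for concave Ru-106/Rh-106
    episcleral plaque applicators, aimed at personalized treatment of small
    intraocular tumors such as juxtapapillary retinoblastoma in infant eyes.
    Provides an allowed-shape Fermi beta source model with selectable gamma
    lines, a condensed-history Monte Carlo transport engine scoring dose in
    water on a 0.1 mm grid with per-voxel statistics, an independent
    deterministic dose-point-kernel engine used for cross-validation and fast
    planning, tilted-placement geometry parameterized by the gap between the
    posterior plaque edge and the eye, certificate-based absolute calibration,
    a distance sweep over six anatomical reference positions, and
    prescription-time and delivered-dose calculations. Synthetic
    manufacturer-style certificates and case-geometry bundles make the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
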