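Package: afmcell
Title: Viscoelastic Force-Curve Analysis and Nanomechanical Mapping of Living Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of atomic force microscopy (AFM) force-volume data from
    living cells. Fits the approach segment of force-distance curves with the
    Hertz spherical-contact model (apparent Young's modulus) and full
    approach-retract records with Ting's hereditary-integral model under
    power-law rheology (E(t) = E1 * t^-alpha plus a Newtonian viscous term),
    including a bottom-effect correction for thin samples bonded to a rigid
    substrate. Reconstructs topography from contact points, performs global
    tilt correction, central-part filtering and per-cell/per-cohort
    aggregation, and provides the companion plate-reader and flow-cytometry
    summaries (kinetics area under the curve, DNA normalization,
    per-experiment z-standardization, phagocytic affinity and capacity).
    A synthetic-data module generates ground-truth force curves, force-volume
    maps of phantom cells, condition cohorts and assay data so that every
    stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    minpack.lm,
    pracma,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
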