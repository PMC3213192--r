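Package: neutraldrift
Title: Neutral-Drift Model of Density-Dependent Clustering and Cell Polarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stochastic particle simulation and analytical machinery for a
    minimal positive-feedback circuit in which signaling molecules (e.g. Cdc42
    and other Rho-family GTPases) cycle between an inactive cytosolic state and
    an active membrane-bound state, with active molecules recruiting inactive
    ones to their own location. Implements the deterministic rate equation for
    the cytosolic density and its transcritical bifurcation structure, the
    exact stationary distribution of the cytosolic molecule count as a one-step
    birth-death process, lateral-diffusion particle simulations on a circular
    membrane with clan (genealogy) tracking and perturbation protocols,
    clan-extinction statistics under neutral drift, an operational polarization
    detector, regime classification and phase-diagram scans, and a
    Brownian-dynamics variant with a finitely diffusing inactive pool in
    sphere, planar and volumetric geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
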