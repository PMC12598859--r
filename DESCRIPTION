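Package: dissipmap
Title: Mapping Local Dissipation and Entropy Production in Driven and
    Active Fluids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Particle-based nonequilibrium simulations and trajectory-ensemble
    statistics for spatially resolved dissipation and entropy production.
    Implements three two-dimensional model systems: a color-field-driven WCA
    fluid in a channel of varying width with thermostatted tethered walls, a
    driven fluid flowing past a disk-shaped obstacle under a Gaussian ergostat,
    and a driven active fluid with Ornstein-Uhlenbeck self-propulsion under an
    isokinetic thermostat.  Time-integrated dissipation is partitioned into
    spatial bins, and the local fluctuation theorem is tested through
    asymmetry functions ln[p(A)/p(-A)] with origin-constrained slope fits and
    the local-surroundings correlation coefficient kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
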