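Package: eggspin
Title: Mechanochemical Simulation and Quantification of Egg-Chamber Rotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the spontaneous onset of rotational migration in the
    Drosophila egg chamber, modelled as an overdamped rigid ellipsoid driven by
    stochastic, Fat2-oriented crawling forces at the basal epithelial surface,
    with mechanosensitive Fat2 concentration dynamics closing a positive
    feedback loop.  Includes the unconstrained spherical variant with a freely
    wandering rotation axis, a stage-1 extension in which an elastic/viscous
    interface with stationary pre-stalk cells selects the anterior-posterior
    axis, ensemble observables (symmetry-breaking direction, onset time, Fat2
    polarization), and the quantification layer used on live-imaging data:
    centroid-track filtering and drift correction, a polar order parameter,
    displacement and migration-rate statistics, and the leading-trailing versus
    lateral Fat2 edge-intensity polarity ratio.  A synthetic-data generator
    produces track and edge tables with the statistical structure of the
    experimental regimes so the whole pipeline is testable without microscopy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
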