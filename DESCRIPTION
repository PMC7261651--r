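Package: shuttlemech
Title: Mechanics and Vascular-Damage Modelling for Neural-Probe Insertion Shuttles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational models for the design of rigid shuttles that deliver
    flexible neural electrode arrays through tough neural membranes. Provides
    parametric probe cross-sections (rectangles and T-beams) with exact area,
    centroid and second moment of area; Euler buckling loads with
    boundary-condition effective-length factors and design-space sweeps; a
    Monte Carlo model of microvascular transection by an arbitrary probe
    footprint randomly placed over a projected 3-D vessel network, with a
    Gaussian summary of per-trial damage counts; a reader and a seeded
    synthetic generator for 3-D microvascular networks; closed-form insertion
    kinematics for linear motion with superimposed uniaxial oscillation; and a
    root-mean-square noise-floor and unit signal-to-noise metric for filtered
    extracellular recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
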