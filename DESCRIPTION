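Package: kinasedyn
Title: Geometric and Interaction Analysis of Kinase MD Trajectories
Version: 0.1.0
Authors@R:
    person("Kinasedyn", "Developers", email = "kinasedyn@example.org",
           role = c("aut", "cre"))
Description: Trajectory analysis toolkit for molecular dynamics studies of
    protein kinase conformational regulation. Implements centre-of-geometry
    segment angles for tracking activation-segment-helix motion relative to
    the kinase hinge and alphaC-helix, inter-subunit cog distance triads for
    dimer-interface stability, replica-aggregated RMSF and RMSD, a single
    cross-system principal component analysis on a shared backbone selection,
    distance-based contact detectors (salt bridges, hydrophobic contacts,
    hydrogen bonds, pi-pi stacking, water bridges) with replica-count
    heatmaps, and DSSP-style secondary-structure occupancy. Ships seeded
    synthetic-trajectory generators (hinged pseudo-kinase, twisting dimer,
    Bernoulli contact pairs, isotropic jitter replicas) that provide analytic
    ground truth for every metric, plus PDB and DCD readers and writers and a
    config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
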