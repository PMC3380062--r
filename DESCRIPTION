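Package: mcmalign
Title: Sorted-String Feature Alignment for Multi-Spectrum LC-MS Data
Version: 0.1.0
Authors@R:
    person("Metabolomics", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Aligns metabolite features (retention time, mass, intensity)
    detected across many LC-MS runs ("maps") into consensus metabolites
    under a constant retention-time tolerance and a ppm-proportional mass
    tolerance. Features are encoded as fixed-width digit-aligned strings
    whose lexicographic order equals numeric order, so a single string
    sort replaces pairwise distance computations; greedy scans of the
    sorted lists produce mass clusters and retention-time clusters, and a
    Map Coverage Maximization loop accepts collision-free consensuses
    from full map coverage down to singletons.  Includes ground-truthed
    two-map and multi-map simulators, alignment quality statistics
    (sensitivity, specificity, per-size prediction errors, cumulative
    alignment curves), and consensus-of-tests differential-metabolite
    detection on the aligned intensity matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
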