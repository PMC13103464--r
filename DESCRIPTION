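Package: scsnet
Title: Multimodal EEG-fNIRS Network Analysis of Frequency-Specific
    Spinal Cord Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for synchronized EEG and fNIRS
    recordings acquired around epidural spinal cord stimulation (SCS):
    signal conditioning (filtering, epoching, artifact rejection,
    spherical-spline channel interpolation, common average reference,
    optical-density conversion, temporal derivative distribution repair,
    modified Beer-Lambert inversion), linear inverse solutions on analytic
    toy leadfields (sLORETA and depth-weighted minimum-norm estimation)
    with atlas-based ROI aggregation, band-wise phase-locking-value and
    Fisher-z hemodynamic connectivity, graph-theoretical metrics integrated
    over a proportional-sparsity grid with degree-preserving null networks,
    and group inference by the network-based statistic and repeated-measures
    ANOVA with FDR and Bonferroni correction. A seeded synthetic-data
    generator with planted connectivity effects makes every stage testable
    without access to patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    igraph,
    pracma,
    MASS,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
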