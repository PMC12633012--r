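Package: alveoniche
Title: AT2 Cell-State Signatures, Spatial Niches and Maturation Scoring
    for the Early Postnatal Lung
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for single-nucleus and targeted spatial
    transcriptomics of the early postnatal distal lung. Implements QC
    filtering and log-normalization, Wilcoxon marker detection with
    percent-expressed and fold-change filters, gene-signature construction
    and binned-control module scoring, assignment of the two mutually
    exclusive alveolar type 2 (AT2) transcriptional states (lipogenic
    FMO5+ vs inflammatory CFTR+), specimen stratification by AT2-state
    abundance with equal-weight compositional analysis, neighborhood
    composition k-means niche detection with cross-section alignment,
    symmetric nearest-neighbor colocalization distances with ANOVA/Tukey,
    distance-band join-count statistics with analytic and permutation
    nulls, developmental maturation on/off scoring, and a seeded synthetic
    data generator that emulates the statistical structure all of these
    assume.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    methods,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
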