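Package: phidyn
Title: Integrated Information Decomposition of Regional Brain Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gaussian minimum-mutual-information Integrated Information
    Decomposition (PhiID-MMI) of parcellated brain time series. Splits the
    time-delayed mutual information of every region pair into sixteen
    information atoms (redundancy, unique, synergy crossed over past and
    future) via a product-lattice cumulative function and Moebius inversion,
    and provides the accompanying group-comparison pipeline: regional sums,
    z-scoring against a reference group, first-principal-component
    projection, region/pair/network-wise Welch and pooled t tests with
    Benjamini-Hochberg false-discovery-rate control, network-label
    permutation tests, taxonomic information modes, and bootstrap confidence
    intervals. Includes a stationary VAR(1) synthetic-cohort generator with
    analytic ground-truth covariances, signal conditioning (zero-phase
    band-pass, TR harmonisation, nuisance regression), and a YAML-configured
    simulate/decompose/analyze/report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'atom-stack.R'
    'cohort-io.R'
    'cohort.R'
    'conditioning.R'
    'group-stats.R'
    'modes.R'
    'parcellation.R'
    'permutation.R'
    'phiid-lattice.R'
    'phiid-pair.R'
    'pipeline.R'
    'utils.R'
    'var-model.R'
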