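Package: flimox
Title: FLIM-FRET Oxygen Mapping and Mitochondrial Nucleic Acid Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts time-correlated single photon counting (TCSPC) image
    stacks into per-pixel oxygen partial pressure (pO2) maps via biexponential
    fluorescence-decay fitting and inversion of a hyperbolic myoglobin-FRET
    calibration curve. Provides lifetime-distribution histograms, high-/low-
    oxygen-consumption subpopulation fractions, the FLIM-based redox ratio
    (FLIRR), and group statistics, together with quantification arithmetic for
    DRIP-qPCR enrichment (2^dCt with dilution correction), mitochondrial DNA
    copy number, and binned/smoothed DRIP-seq coverage on a circular genome.
    A synthetic-data generator with known ground truth stands in for the
    microscope and qPCR instrument so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Rcpp,
    minpack.lm,
    tiff,
    png,
    yaml,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
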