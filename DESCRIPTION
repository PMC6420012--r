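Package: nadflux
Title: Stable-Isotope Flux Assay for NAD+ Synthesis and Breakdown
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of NAD+ turnover in cultured mammalian
    cells from a deuterated-nicotinamide (d4-Nam) labeling assay. Converts
    LC-MS/MS selected-reaction-monitoring peak areas into absolute
    isotopologue amounts via per-analyte calibration curves with
    limit-of-quantification handling, computes the rates of NAD+ synthesis
    (R_S) and breakdown (R_B), absolute intracellular NAD+ concentration via
    mean cell volume, and first-order turnover half-life. Encodes the assay's
    validity requirements (negligible nicotinamide recycling, labeling-time
    linearity, tracer bioavailability equivalence) as executable checks, and
    includes a salvage-pathway kinetic simulator (Michaelis-Menten synthesis
    with NAD+ feedback inhibition of Nampt, first-order breakdown with
    isotope-resolved nicotinamide release) for synthetic-data generation,
    estimator-bias scans, and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
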