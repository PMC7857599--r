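Package: invasim
Title: Invasion Assays in Chemically Mediated Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates microbial communities whose members interact through
    produced and consumed chemical mediators, using a mediator-explicit
    growth model integrated with forward Euler through serial growth-dilution
    cycles. Provides random interaction-network and invader generators,
    community assembly by in silico enrichment, an invasion assay that
    classifies outcomes as resistance, augmentation, displacement or
    disruption, an optional explicit limiting resource, and a battery of
    parameter-sweep experiments with exact Clopper-Pearson binomial
    confidence intervals on outcome frequencies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
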