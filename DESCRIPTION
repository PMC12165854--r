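Package: chromoshard
Title: Simulation and Classification of Chromothripsis-Associated
    Chromosome Amplification
Version: 0.1.0
Authors@R:
    person("chromoshard", "maintainers", email = "maintainers@chromoshard.dev",
           role = c("aut", "cre"))
Description: Tools to simulate derivative chromosomes produced by
    chromothripsis, breakage-fusion-bridge (BFB) cycles and simple
    structural variants, and to analyse the resulting rearrangement
    landscape the way blast-phase myeloproliferative neoplasm (BP-MPN)
    cohorts are analysed: proximity-based clustering of breakpoint
    junctions, chromothripsis-like classification by the four-criteria
    rule (cluster size, fragment-join goodness of fit, interleaved
    events, copy-number oscillations), fold-back inversion detection,
    cohort-level copy-number recurrence and minimally amplified region
    (MAR) derivation, single-cell clonal hierarchy inference with allele
    dropout, and candidate-gene prioritisation combining differential
    expression, differential chromatin accessibility at promoters and
    allele-specific expression skew.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
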