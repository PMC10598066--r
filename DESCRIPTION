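Package: catifunnel
Title: Candidate-Gene Prioritization for Hereditary Cataract Rat Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for prioritizing candidate cataract genes in inbred rat
    strains, combining a two-strain microarray fold-change screen with Venn
    exclusion, a homoscedasticity-gated Student/Welch RT-qPCR validation
    layer, and a multi-stage variant-prioritization funnel (homozygosity,
    sequence-ontology impact class, dual-assembly concordance, non-affected
    strain-panel exclusion, and SSLP-marker-defined locus restriction with
    cross-assembly coordinate estimation). Includes synthetic-data
    generators with planted ground truth so every pipeline stage can be
    exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
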