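Package: SIPquant
Title: Quantitative Stable-Isotope-Probing Metagenomics with Internal
    Standards
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-resolved quantitative stable isotope probing
    (qSIP) metagenomics. Converts per-density-fraction genome coverage into
    absolute abundance by regression against synthetic internal standards
    (sequins), estimates per-genome atom fraction excess with the qSIP and
    delta-BD models including bootstrap confidence intervals and
    multiplicity-adjusted interval calling, identifies isotope incorporators
    with HR-SIP and MW-HR-SIP plus threshold, consensus and sequential
    strategies, screens mishandled gradients with pre-centrifugation
    spike-in quality control, and ships a density-gradient simulator with
    known ground-truth enrichment for validating the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Metagenomics, Microbiome, Sequencing, Software
RoxygenNote: 7.3.3
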