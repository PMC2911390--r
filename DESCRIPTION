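Package: rassig
Title: RAS Pathway Gene-Expression Signature Scoring and Coherent Module
    Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving, scoring and validating two-arm pathway
    activation signatures from gene-expression data, built around a
    RAS/MEK/ERK transcriptional signature. Implements mean-normalization
    of expression matrices to log10 ratios, the up-minus-down composite
    signature score with threshold-zero activation calls, a Fisher-exact
    coherence test of signature structure in independent datasets,
    coherent-module discovery by hierarchical clustering of Pearson
    correlation matrices across multiple cohorts, drug-response
    association utilities (max-variance read-out dose selection,
    score-sensitivity correlation, response contingency tests), and a
    synthetic-data generator with planted signature structure for
    end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    fgsea,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
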