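Package: trlfm
Title: Transfer Rule Learning with Functional Modules for Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns IF-THEN classification rule models from discretized
    gene-expression matrices with a general-to-specific beam search, discovers
    functional modules among relevant genes by spectral clustering of
    ontology-term semantic similarities, and transfers knowledge from source
    datasets (or biomarker lists) to a target dataset by instantiating prior
    rules over functionally mapped target variables that seed the rule
    learner. Includes supervised Bayesian discretization with exact
    dynamic-programming optimization, an abstaining rule-based predictor,
    a stratified cross-validation harness with rank-based AUC, and seeded
    synthetic-fixture generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
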