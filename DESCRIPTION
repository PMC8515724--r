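Package: dropoutBN
Title: Bayesian-Network Causal Analysis of Teenage Pregnancy and School
    Dropout
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete Bayesian-network workflow for adolescent-health
    survey data: preprocessing of interview records (median imputation,
    exclusion, class balancing, binarization), exact inference by variable
    elimination, do-operator interventions with backdoor adjustment and
    average causal effects, MAP profiling, consensus aggregation of
    expert-elicited causal structures, and a calibrated synthetic-record
    generator for fully reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
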