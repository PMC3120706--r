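Package: mirgram
Title: Alignment-Free miRNA Family Classification from n-Gram Feature Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns microRNA precursor or mature sequences to families
    without alignment. Sequences are embedded in a fixed vector space of
    sliding-window n-gram frequencies weighted by a per-type concentration
    factor, and families are learned with a one-vs-all linear max-margin
    classifier. Includes the evaluation protocols used for benchmarking
    (stratified k-fold cross-validation, small-family splits, training-size
    sweeps), synthetic negative-control generators (sequence reversal,
    composition-matched random sequences, mutation-derived families), and a
    command-line interface wiring the pieces into reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
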