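Package: predrep
Title: Prediction-Error Coding in Oddball Sequences via the Information
    Bottleneck
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes optimal low-complexity reduced representations of the
    recent stimulus history in two-tone oddball sequences using the
    Information Bottleneck principle, derives per-trial prediction errors
    (surprise, in bits) from those representations, and fits spike-count
    responses against prediction errors by weighted linear regression with
    permutation-based significance testing.  Includes an analytic
    Beta-Bernoulli model of oddball sequences, a deterministic-annealing
    Information Bottleneck solver, explainable-variance partitioning,
    stimulus-specific adaptation (SSA) indices, and a synthetic-data
    generator with known ground truth for validating every stage of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
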