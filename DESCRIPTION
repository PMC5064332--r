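Package: twinlia
Title: Liability-Threshold Twin Analysis of Ordinal Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classical twin-study analysis of ordinal phenotypes under the
    liability-threshold model. Provides scoring of a four-level ordinal
    depression severity measure from questionnaire answers, simulation of
    monozygotic and dizygotic twin pairs with additive, dominance, shared- and
    random-environment variance components, two-stage polychoric correlation
    estimation from double-entered pair tables, constrained weighted
    least-squares fitting and nested likelihood-ratio comparison of the
    ACE/ADE/AE/CE/DE/E variance-component models, Falconer heritability, and
    Monte-Carlo power analysis for detecting dominance against a false AE
    model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
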