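Package: clinoscreen
Title: Screening Gene-Expression Synergy Between Radiation and Simulated Microgravity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible implementation of a transcriptomic screening
    pipeline for two-stressor (radiation x simulated microgravity) cell
    culture experiments. Provides trimmed-mean scaling-factor normalization
    with counts-per-million output, an exact negative-binomial two-group
    test with conditional maximum-likelihood dispersion estimation, a
    five-step judgement procedure that isolates genes whose radiation
    response is modified by simulated microgravity, log2 heatmap export
    with up/down/no-change group allocation, hypergeometric gene-set
    over-representation on GMT collections, and a negative-binomial count
    simulator that emulates a 36-sample two-stressor factorial design so
    that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    optparse
Config/testthat/edition: 3
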