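Package: securesum
Title: Secure Summation and Distributed Statistics via Additive Secret Sharing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Full-threshold additive arithmetic secret sharing over the
    finite ring Z(2^127-1), a two-round secure-summation protocol driven by
    a finite state machine over a pluggable store-and-forward message bus
    (in-memory or filesystem mailboxes), and a distributed-statistics layer
    that composes secure-sum cycles into common biostatistics (frequency
    tables, chi-square, quartiles, Wilcoxon rank-sum, mean, standard
    deviation, t-test/ANOVA, Pearson correlation) without any party
    revealing its local values. Includes a synthetic-study generator and a
    benchmark harness for message-count and data-volume scaling studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
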