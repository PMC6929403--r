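Package: cernapmi
Title: Competing Endogenous RNA Network Inference via Pointwise Mutual Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs competing endogenous RNA (ceRNA) networks from paired
    tumor/normal expression tables. RNAs are filtered for differential
    expression (fold change and paired t-test), candidate lncRNA-miRNA-mRNA
    triples are restricted by a competition-regulation sign rule and a miRNA
    target map, tumor expression is binarized by equal-frequency (median)
    discretization, and each candidate crosstalk receives a pointwise mutual
    information competition score computed from competition-sample counts.
    Crosstalks with significantly high scores (z-score against the group of
    positive scores, p = erfc(theta/sqrt(2)) < 0.05) are assembled into
    per-miRNA tripartite networks. Includes a synthetic-data generator with
    planted ceRNA triples for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
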