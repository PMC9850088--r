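Package: ucsig
Title: Cross-Species Conserved Transcriptional Signatures of Ulcerative Colitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies transcriptional signatures conserved between mouse
    colitis models and human ulcerative colitis from differential-expression
    result tables. Provides significance/fold-change filtering with
    biotype-specific thresholds, multi-dataset consistency combination with an
    explicit inconsistent partition, ortholog-mediated cross-species overlap
    with direction-concordance classification, cross-tissue core-set
    extraction, genomic-context annotation (lncRNA neighbours, risk-locus
    proximity, miRNA target sets), hypergeometric over-representation
    analysis, combined network-centrality ranking on confidence-scored
    interaction networks, and 2^-ddCt qPCR quantification. A synthetic-data
    generator with planted ground truth makes the full pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    rtracklayer,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
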