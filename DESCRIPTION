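Package: rsnpscan
Title: Genome-Wide Regulatory SNP Detection, Ranking and TFBS Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts regulatory SNPs (rSNPs) genome-wide by allele-swap
    position weight matrix scanning of promoter SNP flanks with the
    MATCH-style matrix similarity score, classifies each SNP-TFBS pair as
    gain, loss, score-change or no-change of a predicted binding site,
    ranks rSNPs by phenotype association with an iterated Boruta
    random-forest consensus, and tests binding-site over-representation in
    promoters of differentially expressed genes against GC-matched
    background promoter sets. Ships a fully deterministic synthetic-data
    generator with scanner-verified truth labels so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
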