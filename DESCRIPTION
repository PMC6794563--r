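Package: thermolnc
Title: Identification, Classification and Target Analysis of Heat-Responsive Long Non-Coding RNAs
Version: 0.1.0
Authors@R: person("thermolnc", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale, fully testable re-implementation of a genome-wide
    lncRNA analysis workflow for two-condition (control vs heat stress)
    strand-specific RNA-seq: candidate filtering from assembled transcripts
    (length, ORF, coding potential, protein-domain evidence, expression),
    strand-aware genomic-context classification (intergenic, antisense, sense,
    intronic), FPKM quantification and exact-test differential expression with
    Benjamini-Hochberg FDR, cis target pairing by genomic windows and trans
    target pairing by an intermolecular RNA-RNA duplex minimum-free-energy
    dynamic program, and hypergeometric pathway enrichment. Ships a synthetic
    transcriptome generator with planted ground truth so every stage is
    verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
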