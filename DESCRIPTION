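Package: retrofunc
Title: Multi-Evidence Functional Annotation of Retrocopies
Version: 0.1.0
Authors@R:
    person("Retrofunc", "Developers", email = "retrofunc@example.org",
           role = c("aut", "cre"))
Description: Annotates retrocopies (retroposed gene copies) with functional
    evidence from bulk transcriptomics and ribosome profiling: TPM-based
    expression filtering and expression-pattern classification, Spearman
    co-expression in two sample-selection modes, ribosome-density calling
    calibrated against a 3'UTR negative-control distribution, six-frame ORF
    discovery with exact peptide matching, miRNA-sponge (ceRNA) testing by
    hypergeometric enrichment of shared target-site families with
    Benjamini-Hochberg correction, strand-aware overlap classification into
    cis/trans natural antisense and transcriptional-interference candidates,
    exon-contribution (exonization) classes, and fusion-breakpoint
    classification. A synthetic-data module plants every signal class with
    machine-readable ground truth so each stage is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
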