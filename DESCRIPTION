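Package: ancref
Title: Ancestral-Like Reference Sequences for Non-Recombining Chromosomes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds an ancestral-like reference sequence for a
    non-recombining chromosome (such as the human Y) by weighted
    maximum parsimony over a fixed dated phylogeny. Reconstructs the
    allele at a focal internal node (the ingroup MRCA) per polymorphic
    site with branch-length-scaled substitution costs, scores each
    reconstruction with a per-locus uncertainty score, edits a template
    FASTA back to the reconstructed ancestral states, polarizes VCF
    variants into ancestral and derived alleles against the resulting
    site table, and provides molecular-clock age estimates
    (coverage-normalized SNP counts, time of split, focal-node age).
    Includes a Kimura-style sequence simulator over dated trees so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
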