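Package: somaticsigs
Title: Mutational Signature and Pattern Analysis of Somatic SNVs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds 96-channel trinucleotide mutation count matrices from
    somatic single-nucleotide variant calls (VCF) and a reference genome
    (FASTA), extracts mutational signatures de novo by non-negative matrix
    factorization, quantifies the contribution of known signatures by
    non-negative least squares refitting, tests transcriptional and
    replicative strand asymmetries with exact conditional tests, measures
    regional enrichment and depletion of mutations against surveyed
    (callable) loci with one-sided binomial tests, and computes
    intermutation-distance (rainfall) series. A deterministic synthetic-data
    module simulates toy genomes, stranded gene annotations and SNV
    catalogues from known signature mixtures so the whole pipeline can be
    exercised end to end without external downloads. A command-line
    interface exposes the pipeline for shell use.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    ggplot2,
    rlang,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
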