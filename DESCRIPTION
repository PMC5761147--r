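Package: terpscan
Title: Profile-HMM Identification and Classification of the Plant Terpenome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and classifies terpene synthases (TPS) and prenyl
    transferases (PT) in protein or EST sequence data. Builds profile hidden
    Markov models from curated family alignments using Henikoff
    position-based sequence weighting, scans queries against a bank of 13
    sub-family profiles in parallel and assigns the sub-family of the
    highest-scoring profile. Diterpene synthases are further sub-classified
    by class I (DDxxD/E, NSE/DTE) and class II (DxDD) signature motifs.
    Includes six-frame translation of EST input with Gumbel-calibrated
    E-value filtering, benchmark utilities (per-profile sensitivity and
    accuracy before and after combining profiles by top score), tandem
    gene-cluster detection along chromosomes with a significance test, and
    a synthetic-data module that generates labelled protein families and
    genomes so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
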