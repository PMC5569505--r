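Package: synmag
Title: Synthetic Metagenome Communities and Genome-Resolved Binning Workflows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building ground-truthed synthetic metagenome
    communities (Markov-chain genomes, assembly-like scaffold fragmentation,
    contaminant injection, paired-end read simulation, single-copy marker
    placement, multi-database annotation records) and for the downstream
    genome-resolved analyses they exercise: canonical tetranucleotide
    frequency profiling and self-organizing-map binning of scaffolds,
    marker-based bin completeness and duplication estimates with
    quality gates and scaffold-level decontamination, exact full-length
    read recruitment with genome-size- and depth-normalized relative
    abundance, consensus-based metabolic pathway calling with domain-level
    gene-family statistics, and concatenated marker-gene supermatrices with
    neighbor-joining trees and bootstrap support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    mclust,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
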