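Package: bayestx
Title: Bayesian Transcriptome Assembly from Spliced RNA-Seq Alignments
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reference-based transcriptome assembly for paired-end RNA-seq.
    Builds per-locus splice graphs from spliced alignments, enumerates
    transcript candidates by depth-first path search with coverage pruning,
    and infers which candidates are expressed with a Gibbs sampler under a
    spike-and-slab Bernoulli-Dirichlet model of the sequencing process.
    Reports per-transcript confidence (posterior expression frequency),
    posterior-mean abundance and expected fragment counts, and writes the
    filtered assembly as GTF. Includes a simulator for the generative model
    and assembly evaluation by intron-chain matching.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    Rsamtools,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
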