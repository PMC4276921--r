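Package: ngsdesk
Title: Desk-Scale Toolkit for NGS Taxonomic Census, SNV Profiling,
    Profile Clustering, Quasispecies and Recombination Analysis
Version: 0.1.0
Authors@R:
    person("ngsdesk", "developers", email = "ngsdesk@example.org",
           role = c("aut", "cre"))
Description: A self-contained toolkit for short-read sequence analysis at
    desk scale: subsampling-based taxonomic census of metagenomic read
    sets, per-position pileup SNV profiling with traceable evidence,
    hierarchical clustering of SNV frequency profiles with phylogram
    (Newick) output, SNV-based phylogenetics including shrunk-genome
    concatenation of variant flanking windows, quasispecies clone
    discovery by mutation co-occurrence linkage within reads, and
    recombination breakpoint detection from read coverage across mutually
    aligned reference genomes. Includes a deterministic read simulator
    (diverged genome mixtures, haplotype mixtures, recombinants) and a
    minimal seed-and-extend read mapper so every stage can be exercised
    without external data; external alignments are accepted as SAM.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    ape,
    phangorn,
    IRanges,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
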