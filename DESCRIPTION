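Package: hetasm
Title: Heterozygosity-Aware Draft Genome Assembly and Comparative Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of the heterozygosity-aware
    short-read assembly strategy used for highly heterozygous invertebrate
    genomes: k-mer spectrum estimation of genome size and heterozygosity,
    de Bruijn unitig construction with per-contig read depth, depth-based
    identification of heterozygous contigs, read-pair bubble clustering and
    collapse to a single haplotype, hierarchical mate-pair scaffolding with
    duplicate masking, paired-read gap closing, assembly QC statistics
    (N50, alignment coverage), and comparative statistics (repeat-content
    versus genome-size regression, intron/exon accounting).  Includes a
    diploid genome and read simulator so every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    Biostrings,
    IRanges,
    igraph
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
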